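#' Planar mesh of two nanoparticle dipoles flanking a hydroxyapatite particle
#'
#' Square gel domain with two circular dipole holes on the vertical
#' (field) axis, placed symmetrically about the centre, and a rectangular
#' hydroxyapatite subdomain at the centre, optionally rotated about its
#' centroid. The domain is split into three horizontal bands, each meshed
#' with the star-ray scheme; cut-line node tables keep the bands conforming,
#' and the rectangle corners are sampled exactly so its area is exact.
#'
#' @param hap_length particle length (long axis, vertical at 0 deg), m.
#' @param hap_width particle width, m (default 50 nm).
#' @param rotation_deg rotation of the particle about its centroid, degrees
#'   (0 = vertical, 90 = horizontal).
#' @param menp_spacing centre-to-centre distance of the two dipoles, m.
#' @param gel_side side of the square gel domain, m (default 1 um).
#' @param h element size near the particles, m.
#' @param menp_radius dipole particle radius, m (default 70 nm).
#' @param delta_far element size on the outer boundary and band cuts, m.
#' @return planar `mp_mesh` with subdomains `gel`, `hap`; boundary tags
#'   `outer_top`, `outer_bottom`, `outer_side`, `particle_surface_1` (upper),
#'   `particle_surface_2` (lower) and the interior interface `hap_surface`.
#' @export
make_hap_2d_mesh <- function(hap_length = 100e-9, hap_width = 50e-9,
                             rotation_deg = 0, menp_spacing = 0.65e-6,
                             gel_side = 1e-6, h = 5e-9,
                             menp_radius = 70e-9, delta_far = 50e-9) {
  L <- gel_side
  hw <- hap_width / 2; hl <- hap_length / 2
  a <- rotation_deg * pi / 180
  corners_body <- rbind(c(hw, hl), c(-hw, hl), c(-hw, -hl), c(hw, -hl))
  R2 <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  corners <- corners_body %*% t(R2)
  ymax <- max(abs(corners[, 2])); xmax <- max(abs(corners[, 1]))
  inner_surf <- menp_spacing / 2 - menp_radius
  if (ymax >= inner_surf) {
    stop("HAP particle (|y| up to ", signif(ymax * 1e9, 4),
         " nm) collides with MENP surface at ",
         signif(inner_surf * 1e9, 4), " nm")
  }
  if (xmax >= L / 2 || menp_spacing / 2 + menp_radius >= L / 2) {
    stop("particle geometry does not fit inside the gel domain")
  }
  yc <- (ymax + inner_surf) / 2
  rho_hap <- rect_rho(hw, hl, rotation_deg)

  # cut-line and edge node tables (shared between bands)
  xmid <- seq_spaced(-L / 2, L / 2, delta_far)    # y = +-yc cut lines
  ymid <- seq_spaced(-yc, yc, delta_far)          # x = +-L/2, middle band
  # insert the exit points of the rectangle-corner rays
  phi_c <- atan2(corners[, 2], corners[, 1])
  rho_band <- rect_rho(L / 2, yc, 0)
  for (ph in phi_c) {
    ex <- rho_band(ph) * c(cos(ph), sin(ph))
    if (abs(abs(ex[2]) - yc) < 1e-9 * yc) {
      if (min(abs(xmid - ex[1])) > 1e-12) xmid <- sort(c(xmid, ex[1]))
    } else {
      if (min(abs(ymid - ex[2])) > 1e-12) ymid <- sort(c(ymid, ex[2]))
    }
  }
  ytop <- seq_spaced(yc, L / 2, delta_far)        # x = +-L/2, outer bands
  xdom <- seq_spaced(-L / 2, L / 2, delta_far)    # y = +-L/2 domain edges

  band_perim <- function(bot, rgt, top, lft) {
    perim <- rbind(bot[-nrow(bot), ], rgt[-nrow(rgt), ],
                   top[-nrow(top), ], lft[-nrow(lft), ])
    perim
  }
  band_tags <- function(nb, nr, nt, nl, tags) {
    c(rep(tags[1], nb - 1L), rep(tags[2], nr - 1L),
      rep(tags[3], nt - 1L), rep(tags[4], nl - 1L))
  }

  # middle band: gel ring around the HAP rectangle
  bot <- cbind(xmid, -yc); rgt <- cbind(L / 2, ymid)
  top <- cbind(rev(xmid), yc); lft <- cbind(-L / 2, rev(ymid))
  mid <- ray_band_mesh(
    center = c(0, 0), rho_fun = rho_hap,
    perim = band_perim(bot, rgt, top, lft),
    outer_tags = band_tags(nrow(bot), nrow(rgt), nrow(top), nrow(lft),
                           c(NA, "outer_side", NA, "outer_side")),
    h_near = h, subdomain = "gel", inner_tag = "hap_surface"
  )
  # HAP interior, conforming to the ring nodes of the middle band
  perim_mid <- band_perim(bot, rgt, top, lft)
  phi <- atan2(perim_mid[, 2], perim_mid[, 1])
  rin <- rho_hap(phi)
  ring <- cbind(rin * cos(phi), rin * sin(phi))
  hap <- star_interior_mesh(c(0, 0), ring, h = min(h, hw / 2),
                            subdomain = "hap", boundary_tag = "hap_surface")

  # upper and lower dipole bands
  menp_band <- function(sgn, pid) {
    if (sgn > 0) {
      bot <- cbind(xmid, yc); rgt <- cbind(L / 2, ytop)
      top <- cbind(rev(xdom), L / 2); lft <- cbind(-L / 2, rev(ytop))
      tags <- c(NA, "outer_side", "outer_top", "outer_side")
    } else {
      bot <- cbind(xdom, -L / 2); rgt <- cbind(L / 2, -rev(ytop))
      top <- cbind(rev(xmid), -yc); lft <- cbind(-L / 2, -ytop)
      tags <- c("outer_bottom", "outer_side", NA, "outer_side")
    }
    ray_band_mesh(
      center = c(0, sgn * menp_spacing / 2),
      rho_fun = disc_rho(menp_radius),
      perim = band_perim(bot, rgt, top, lft),
      outer_tags = band_tags(nrow(bot), nrow(rgt), nrow(top), nrow(lft), tags),
      h_near = h, subdomain = "gel",
      inner_tag = paste0("particle_surface_", pid)
    )
  }
  merge_meshes(list(mid, hap, menp_band(+1, 1L), menp_band(-1, 2L)),
               coord = "planar")
}
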