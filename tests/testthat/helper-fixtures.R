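# shared fixtures, built in code at test time

default_cfg <- carm_config()

# large plane tilted by `theta_deg` about the patient z axis, crossing the
# PA beam axis at y = y0 (two triangles; refine before area work)
tilted_plane <- function(theta_deg, y0 = -110, half_mm = 450) {
  th <- theta_deg * pi / 180
  v <- cbind(c(-1, 1, 1, -1) * half_mm, 0, c(-1, -1, 1, 1) * half_mm)
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  v <- v %*% t(rot)
  v[, 2] <- v[, 2] + y0
  surface_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)), provenance = "tilted plane")
}

# axis-aligned cube of side `s`, centred at `center`
cube_mesh <- function(s, center = c(0, 0, 0)) {
  ph <- make_slab(width_mm = s, length_mm = s, thickness_mm = s)
  m <- ph$mesh
  bb <- apply(m$vertices, 2, range)
  translate_mesh(m, center - colMeans(bb))
}

# sphere of radius r centred at `center`
sphere_mesh <- function(r, center = c(0, 0, 0), subdiv = 4) {
  s <- beamskin:::icosphere(subdiv)
  s$vertices <- s$vertices * r
  translate_mesh(s, center)
}
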