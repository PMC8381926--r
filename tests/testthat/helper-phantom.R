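# shared fixtures, generated in code at test time

# reduced phantom for unit tests: 104^3 voxels (62.4 mm FOV) around a 14-mm
# cup; keeps a single generate/analyse cycle around a second
small_spec <- function(seed, ...) {
  phantom_spec(volume_shape = c(104L, 104L, 104L),
               cup_outer_radius_mm = 14, seed = as.integer(seed), ...)
}

# clinical-scale phantom used by the acceptance suite: default 24-mm cup at
# the paper protocol's 0.6-mm voxels and 20 HU noise, in a 144^3 grid so the
# whole scene survives a 4 mm / 3 degree repositioning
acceptance_spec <- function(seed, ...) {
  phantom_spec(volume_shape = c(144L, 144L, 144L), seed = as.integer(seed),
               ...)
}

random_rigid <- function(seed, max_t = 10, max_r = 20) {
  withr::with_seed(as.integer(seed), {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    ang <- stats::runif(1, -max_r, max_r)
    tr <- stats::runif(3, -max_t, max_t)
    rigid_transform(ctmotion:::rotation_about_axis(axis, ang), tr)
  })
}

# transform discrepancy as (translation mm, rotation degrees)
rt_discrepancy <- function(a, b) {
  d <- rt_compose(rt_inverse(a), b)
  c(t = sqrt(sum(d$t^2)), r = rt_rotation_angle(d))
}

max_abs_6dof_error <- function(result, true_migration) {
  truth <- decompose_6dof(true_migration, result$center_of_mass_mm)
  c(t = max(abs(result$translations_mm - truth$translations_mm)),
    r = max(abs(result$rotations_deg - truth$rotations_deg)))
}
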