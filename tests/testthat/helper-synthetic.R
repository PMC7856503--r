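# Shared synthetic fixtures. The default beam_spec() emulates the iViewGT
# study conditions (1024x1024 panel, 0.4 mm pitch, SDD 1600 -> 0.25 mm at
# isocenter, 10x10 cm, 100 MU); `small_spec()` keeps the same isocenter pixel
# size on a 512x512 panel (128 mm field of view) for the repeated-replicate
# property tests.
small_spec <- function(...) {
  beam_spec(grid = c(512, 512), ...)
}

# half an isocenter pixel at the study conditions
HALF_PIXEL <- 0.25 / 2

# a well-behaved averaged X profile through a generated field
profile_of <- function(spec) {
  img <- generate_portal_image(spec)$image
  extract_profile(img, "X")
}

# mirror a profile about a position (positions negated and reversed)
mirror_profile <- function(p, about = 0) {
  beam_profile(p$axis, 2 * about - rev(p$positions), rev(p$values))
}

# flat 16-sample region at 1 mm step, values editable by index
flat_region <- function(values = rep(100, 16)) {
  beam_profile("X", seq(-7.5, 7.5, by = 1), values)
}

# uniform synthetic image with given constant value
constant_image <- function(value = 50, n = 64, spacing = 0.4, sdd = 1600, sad = 1000) {
  portal_image(matrix(value, n, n),
    pixel_spacing_detector = spacing, sdd = sdd, sad = sad, mu = 100
  )
}
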