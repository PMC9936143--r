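# Shared fixtures, built once per run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small synthetic HRTF set on an icosahedral grid (fast to build)
ico_hrtf <- function() cached("ico_hrtf", function()
  make_synthetic_hrtf(directions = mesh_directions(icosahedron()),
                      n_samples = 128, seed = 3))

# dense set interpolated from the icosahedral grid (642 directions)
dense_hrtf <- function() cached("dense_hrtf", function()
  interpolate_to_dense(ico_hrtf()))

# full 91-direction synthetic listener
listener_hrtf <- function() cached("listener_hrtf", function()
  make_synthetic_hrtf(seed = 7))

# compact target grid whose FBC-eligible targets sit far from the
# front/back boundary (reversal labels are unambiguous there)
recovery_grid <- function() cached("recovery_grid", function()
  make_source_grid(list(
    list(lateral_deg = 0, polar_deg = c(-30, 0, 30, 150, 180, 210)),
    list(lateral_deg = 30, polar_deg = c(0, 30, 180)),
    list(lateral_deg = -30, polar_deg = c(0, 30, 180)))))

# linear magnitude spectra (full FFT grid) excluding the Nyquist bin, where
# a real-output fractional delay necessarily carries a cos(pi * d) factor
mag_db_ex_nyquist <- function(set) {
  m <- dynloc:::hrtf_magnitude(set)
  n <- dim(m)[1]
  drop_bin <- if (n %% 2 == 0) n / 2 + 1 else integer(0)
  20 * log10(m[setdiff(seq_len(n), drop_bin), , , drop = FALSE])
}

expect_direction_equal <- function(d1, d2, tol_deg = 1e-9) {
  expect_lt(max(angular_distance(d1, d2)), tol_deg)
}
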