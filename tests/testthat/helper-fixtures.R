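# Shared fixtures: explicit extinction values everywhere so no result depends
# silently on the package default table.

test_eps <- function() {
  extinction_table(c(756, 797), eps_hbo2 = c(620, 766), eps_hb = c(1590, 761))
}

# compact two-sphere phantom: hypoxic lesion + oxygenated vessel, zero
# background absorption (uniform dual-sided fluence)
two_sphere_phantom <- function(grid = c(64, 64, 64), pitch = 0.5,
                               radius = 1.0, thc = 1e-4) {
  spec <- phantom_spec(grid, pitch, background_mua = c("756" = 0, "797" = 0),
                       structures = list(
                         lesion_sphere(c(16, 16, 12), radius, thc, 0.60, id = "lesion"),
                         lesion_sphere(c(16, 16, 20), radius, thc, 0.85, id = "vessel")))
  build_breast_phantom(spec, seed = 1)
}

# small array for fast forward/recon unit tests
small_array <- function(...) {
  detector_array(n_horizontal = 7, n_vertical = 7, center_mm = c(8, 8), ...)
}

# draw a filled disk in a logical matrix
disk_mask <- function(n, center, r) {
  X <- matrix(seq_len(n), n, n)
  Y <- t(X)
  (X - center[1])^2 + (Y - center[2])^2 <= r^2
}

# cached demo pipeline run shared by pipeline and acceptance tests
.demo_cache <- new.env(parent = emptyenv())
demo_run_cached <- function() {
  if (is.null(.demo_cache$manifest)) {
    cfg <- demo_run_config(file.path(tempdir(), "pamoxi-demo"), seed = 1)
    .demo_cache$config <- cfg
    .demo_cache$manifest <- run_pipeline(cfg)
  }
  list(config = .demo_cache$config, manifest = .demo_cache$manifest)
}
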