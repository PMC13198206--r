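# Shared fixtures, built in code.

# A tiny RGB tile with deterministic content.
toy_tile <- function(n = 8, value = c(100, 50, 200), slide_id = "s1") {
  px <- array(rep(value, each = n * n), c(n, n, 3))
  rgb_tile(px, slide_id = slide_id)
}

# Forward-simulate OD pixels from known stain vectors with a tissue-like
# concentration mixture: near-pure nuclei pixels, near-pure stroma pixels,
# and mixed pixels. This is the independent oracle for basis recovery.
simulate_od_pixels <- function(n, v_h, v_e, noise_sd = 0) {
  kind <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  a_h <- ifelse(kind == 1, runif(n, 0.3, 1),
                ifelse(kind == 2, runif(n, 0, 0.1), runif(n, 0.05, 1)))
  a_e <- ifelse(kind == 1, runif(n, 0, 0.1),
                ifelse(kind == 2, runif(n, 0.3, 1), runif(n, 0.05, 1)))
  od <- outer(a_h, v_h) + outer(a_e, v_e)
  if (noise_sd > 0) od <- od + matrix(rnorm(3 * n, 0, noise_sd), ncol = 3)
  od
}

# Random ground-truth stain pair with angles in the stated ranges, built in
# the canonical plane.
random_truth_basis <- function() {
  canon <- fixed_default_basis()
  th_h <- runif(1, -60, -10) * pi / 180
  th_e <- runif(1, 10, 60) * pi / 180
  vx <- canon$axes[, 1]; vy <- canon$axes[, 2]
  list(v_h = cos(th_h) * vx + sin(th_h) * vy,
       v_e = cos(th_e) * vx + sin(th_e) * vy)
}

# Desk training profile used by the acceptance comparison (criteria 5/6):
# the package's desk defaults (published loss weights, sqrt(D)-scaled
# margin, batch-sum contrastive, full-run lambda_U ramp) at a schedule
# scaled down from the stated 100 x 15 budget to fit the suite's CPU
# budget.
acceptance_config <- function(seed, variant) {
  desk_config(tile_size = 64, n_classes = 3, seed = seed,
              iterations_per_epoch = 50, max_epochs = 8, patience_epochs = 8,
              use_mixup = variant != "supervised",
              use_contrastive = variant == "classm")
}

# Small in-memory dataset shared by training-level tests (built once).
small_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- generate_dataset(n_slides = 5, n_labeled_per_class = 6,
                              n_unlabeled = 30, n_val_per_class = 4,
                              n_test_per_class = 4, size = 48, seed = 404)
    }
    ds
  }
})
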