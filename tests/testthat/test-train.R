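test_that("balanced_batch reproduces the published batch compositions", {
  rng <- rng_stream(1)
  # 4-class profile: 64 = 32 labeled (8 x 4) + 32 unlabeled
  cfg4 <- train_config(batch_size = 64, labeled_per_class = 8, n_classes = 4)
  pools4 <- lapply(1:4, function(ci) 100 * ci + 1:50)
  # 3-class profile: 64 = 33 labeled (11 x 3) + 31 unlabeled
  cfg3 <- train_config(batch_size = 64, labeled_per_class = 11, n_classes = 3)
  pools3 <- lapply(1:3, function(ci) 100 * ci + 1:50)
  unlab <- 1000 + 1:200
  for (draw in 1:1000) {
    b4 <- balanced_batch(pools4, unlab, cfg4, rng)
    b3 <- balanced_batch(pools3, unlab, cfg3, rng)
    if (draw <= 5 || draw %% 100 == 0) {
      expect_equal(nrow(b4$labeled), 32)
      expect_equal(length(b4$unlabeled), 32)
      expect_equal(unname(table(b4$labeled$class_idx)), rep(8L, 4),
                   ignore_attr = TRUE)
      expect_equal(nrow(b3$labeled), 33)
      expect_equal(length(b3$unlabeled), 31)
      expect_equal(unname(table(b3$labeled$class_idx)), rep(11L, 3),
                   ignore_attr = TRUE)
    }
    # cheap invariant on every draw
    stopifnot(nrow(b4$labeled) == 32, length(b4$unlabeled) == 32,
              nrow(b3$labeled) == 33, length(b3$unlabeled) == 31)
  }

  # small class pools are sampled with replacement
  tiny <- list(c(1, 2), 100 + 1:50, 200 + 1:50, 300 + 1:50)
  b <- balanced_batch(tiny, unlab, cfg4, rng)
  expect_equal(sum(b$labeled$class_idx == 1), 8)
  expect_true(all(b$labeled$idx[b$labeled$class_idx == 1] %in% c(1, 2)))

  expect_error(balanced_batch(list(integer(0), 1:5), unlab,
                              train_config(n_classes = 2, labeled_per_class = 8),
                              rng),
               class = "classm_config_error")
})

test_that("make_views honors view modes and delegation", {
  cfg <- desk_config(tile_size = 32, n_classes = 3,
                     view_mode = "RedGreen")
  red <- rgb_tile(array(rep(c(255, 0, 0), each = 16), c(4, 4, 3)))
  pair <- make_views(red, NULL, cfg)
  expect_true(all(pair$h == 1))
  expect_true(all(pair$e == 0))

  sl <- slide_spec("v1", seed = 2)
  r <- render_tile(sl, default_textures()$benign, size = 32, seed = 1)
  bases <- fit_slide_bases(list(r$tile))
  cfg_he <- desk_config(tile_size = 32, n_classes = 3)
  direct <- separate_tile(r$tile, bases$v1)
  via <- make_views(r$tile, bases$v1, cfg_he)
  expect_identical(via$h, direct$h)

  # switching adaptive stains off changes outputs on a drifted slide
  cfg_fixed <- desk_config(tile_size = 32, n_classes = 3,
                           use_adaptive_stains = FALSE)
  via_fixed <- make_views(r$tile, bases$v1, cfg_fixed)
  expect_gt(mean(abs(via_fixed$h - via$h)), 1e-4)
})

test_that("evaluation reports match hand arithmetic on confusion matrices", {
  cm <- matrix(c(90, 10, 50, 50), 2, 2, byrow = TRUE)
  rep_ <- eval_report_from_confusion(cm)
  expect_equal(unname(rep_$recall), c(0.9, 0.5))
  expect_equal(rep_$balanced_accuracy, 0.7)

  perfect <- diag(c(10, 20, 30))
  rp <- eval_report_from_confusion(perfect)
  expect_equal(rp$balanced_accuracy, 1)
  expect_equal(unname(rp$f_score), rep(1, 3))

  # duplicating every tile of one class leaves balanced accuracy unchanged
  cm2 <- cm; cm2[1, ] <- cm2[1, ] * 2
  expect_equal(eval_report_from_confusion(cm2)$balanced_accuracy, 0.7)

  # random confusion matrices against an independent recomputation
  set.seed(17)
  for (i in 1:20) {
    m <- matrix(rpois(9, 20), 3, 3)
    r <- eval_report_from_confusion(m)
    expect_equal(r$balanced_accuracy, mean(diag(m) / rowSums(m)))
  }

  expect_warning(eval_report_from_confusion(matrix(c(5, 1, 0, 0), 2, 2,
                                                   byrow = TRUE)),
                 "absent")
})

test_that("supervised reduction: train_step equals a plain CE step", {
  ds <- small_dataset()
  cfg <- desk_config(tile_size = 48, n_classes = 3, seed = 5,
                     use_mixup = FALSE, use_contrastive = FALSE,
                     use_rgb_aug = FALSE)
  td <- classm:::prepare_training_data(ds, cfg)
  model <- dual_encoder(cfg$encoder, cfg$feature_dim, 3, seed = 5)
  opt <- rmsprop_init(model, lr = cfg$lr)
  batch <- balanced_batch(td$labeled_by_class, integer(0), cfg, rng_stream(1))
  st <- train_step(model, opt, td, batch, cfg, rng_stream(2))
  expect_equal(st$losses$unlabeled, 0)
  expect_equal(st$losses$contrastive, 0)

  # reference supervised CE on the same augmented batch and parameters
  rng_ref <- rng_stream(2)
  pairs <- lapply(seq_len(nrow(batch$labeled)), function(r)
    classm:::tile_to_pair(td$tiles[[td$manifest$tile_path[batch$labeled$idx[r]]]],
                          td$bases, cfg, rng_ref))
  h <- stack_channels(lapply(pairs, `[[`, "h"))
  e <- stack_channels(lapply(pairs, `[[`, "e"))
  fw <- model_forward(model, h, e)
  y <- diag(3)[batch$labeled$class_idx, ]
  ce_ref <- -mean(rowSums(y * log(pmax(fw$probs, 1e-8))))
  expect_equal(st$losses$ce, ce_ref, tolerance = 1e-6)
  expect_equal(st$losses$total, ce_ref, tolerance = 1e-6)
})

test_that("train_step is deterministic under a fixed seed", {
  ds <- small_dataset()
  cfg <- desk_config(tile_size = 48, n_classes = 3, seed = 5)
  td <- classm:::prepare_training_data(ds, cfg)
  one <- function() {
    model <- dual_encoder(cfg$encoder, cfg$feature_dim, 3, seed = 5)
    opt <- rmsprop_init(model, lr = cfg$lr)
    rng <- rng_stream(77)
    batch <- balanced_batch(td$labeled_by_class, td$unlabeled_pool, cfg, rng)
    train_step(model, opt, td, batch, cfg, rng)$losses
  }
  expect_identical(one(), one())
})

test_that("fit stops on patience and records the best epoch", {
  ds <- small_dataset()
  cfg <- desk_config(tile_size = 48, n_classes = 3, seed = 3,
                     iterations_per_epoch = 1, max_epochs = 20,
                     patience_epochs = 1, lr = 0)  # lr 0: metric constant
  run <- fit(ds, cfg, probe_size = 0)
  expect_length(run$log, 2)  # epoch 1 sets the best; epoch 2 triggers patience
  expect_equal(run$best_epoch, 1)
  bas <- vapply(run$log, `[[`, numeric(1), "val_balanced_accuracy")
  expect_equal(run$best_balanced_accuracy, max(bas))
})

test_that("predict_tiles emits one simplex row per manifest tile", {
  ds <- small_dataset()
  cfg <- desk_config(tile_size = 48, n_classes = 3, seed = 2)
  td <- classm:::prepare_training_data(ds, cfg)
  model <- dual_encoder(cfg$encoder, cfg$feature_dim, 3, seed = 2)
  out_path <- withr::local_tempfile(fileext = ".csv")
  preds <- predict_tiles(model, ds, cfg, out_path = out_path, split = "val",
                         bases = td$bases)
  tab <- read.csv(out_path, check.names = FALSE)
  expect_equal(nrow(tab), sum(ds$manifest$split == "val"))
  pcols <- grep("^prob_", names(tab))
  expect_equal(rowSums(tab[, pcols]), rep(1, nrow(tab)), tolerance = 1e-6)
  expect_true(all(tab$predicted %in% ds$class_names))
})

test_that("the CLI covers simulate, fit-stains and separate end to end", {
  dir <- withr::local_tempdir()
  tiles_dir <- file.path(dir, "tiles")
  cli_main(c("simulate", "--out", tiles_dir, "--seed", "3"))
  # default simulate profile is larger; regenerate small for the rest
  unlink(tiles_dir, recursive = TRUE)
  generate_dataset(out_dir = tiles_dir, n_slides = 3, n_labeled_per_class = 2,
                   n_unlabeled = 2, n_val_per_class = 1, n_test_per_class = 1,
                   size = 32, seed = 3)
  basis_json <- file.path(dir, "bases.json")
  cli_main(c("fit-stains", "--tiles", tiles_dir,
             "--manifest", file.path(tiles_dir, "manifest.csv"),
             "--out", basis_json))
  expect_true(file.exists(basis_json))
  sep_dir <- file.path(dir, "sep")
  cli_main(c("separate", "--tiles", tiles_dir,
             "--manifest", file.path(tiles_dir, "manifest.csv"),
             "--basis", basis_json, "--out", sep_dir))
  outs <- list.files(sep_dir)
  expect_equal(length(outs), 2 * 14)  # H and E per tile (14 manifest rows)
  img <- read_channel_pgm(file.path(sep_dir, outs[1]))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("the CLI trains, evaluates and predicts from a YAML config", {
  dir <- withr::local_tempdir()
  tiles_dir <- file.path(dir, "tiles")
  generate_dataset(out_dir = tiles_dir, n_slides = 4, n_labeled_per_class = 3,
                   n_unlabeled = 6, n_val_per_class = 2, n_test_per_class = 2,
                   size = 32, seed = 12)
  cfg <- yaml::read_yaml(system.file("extdata", "train-desk.yaml",
                                     package = "classm"))
  cfg$iterations_per_epoch <- 2
  cfg$max_epochs <- 2
  cfg$patience_epochs <- 2
  cfg$augment$crop <- 24
  cfg_path <- file.path(dir, "train.yaml")
  yaml::write_yaml(cfg, cfg_path)
  run_dir <- file.path(dir, "run")
  cli_main(c("train", "--config", cfg_path, "--tiles", tiles_dir,
             "--out", run_dir))
  expect_true(file.exists(file.path(run_dir, "best.rds")))
  expect_true(file.exists(file.path(run_dir, "train_log.jsonl")))
  log <- readLines(file.path(run_dir, "train_log.jsonl"))
  expect_length(log, 2)
  preds_path <- file.path(dir, "preds.csv")
  cli_main(c("predict", "--checkpoint", file.path(run_dir, "best"),
             "--config", cfg_path, "--tiles", tiles_dir,
             "--out", preds_path))
  preds <- read.csv(preds_path)
  expect_equal(nrow(preds), 27)  # all manifest rows
})
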