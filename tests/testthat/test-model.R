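# Prediction head, loss, schedule, metrics, training behaviour, dropout,
# checkpointing and attribution export.

test_that("prediction head matches sigmoid closed forms", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  f <- cfg$hidden
  # zero relation vector: dot product 0 -> P = 0.5
  expect_equal(predict_interaction(rnorm(f), rnorm(f), rep(0, f), params), 0.5)
  # engineered dot product ln 3 -> P = 0.75
  pe <- params
  pe$fw_W1[] <- 0; pe$fw_b1[] <- 1      # hidden = 1 everywhere
  pe$fw_W2[] <- 0; pe$fw_W2[1L, ] <- 1 / f
  pe$fw_b2[] <- 0                        # output = (1, 0, 0, ...)
  r <- c(log(3), rep(0, f - 1L))
  expect_equal(predict_interaction(rnorm(f), rnorm(f), r, pe), 0.75)
  # monotone in the dot product
  probs <- vapply(c(-2, -1, 0, 1, 2), function(s) {
    predict_interaction(rnorm(f), rnorm(f), c(s, rep(0, f - 1L)), pe)
  }, 1)
  expect_true(all(diff(probs) > 0))
})

test_that("binary cross-entropy matches closed forms", {
  expect_equal(bce_loss(rep(0.5, 10L), rep(c(0, 1), 5L)), log(2))
  expect_equal(bce_loss(0.8, 1), -log(0.8))
  # perfect-prediction limit under clipping stays finite and near zero
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_true(is.finite(bce_loss(0, 1)))
  expect_error(bce_loss(c(0.5, 0.5), 1), "equal length")
})

test_that("learning-rate schedule is exactly exponential", {
  expect_equal(lr_schedule(1e-3, 5), 1e-3 * 0.96^5)
  expect_equal(lr_schedule(1e-3, 0), 1e-3)
  expect_equal(lr_schedule(0.01, 0:3, decay = 0.5), c(0.01, 0.005, 0.0025, 0.00125))
})

test_that("classification metrics match hand-enumerated and library values", {
  # ranking by hand: labels (1,1,0,0), probs (0.9,0.4,0.6,0.1)
  # pairs won: (0.9>0.6), (0.9>0.1), (0.4<0.6) lost, (0.4>0.1) -> AUC 0.75
  m <- ddi_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(m$auc, 0.75)
  # thresholded at 0.5: predictions (1,0,1,0) -> 2 of 4 correct
  expect_equal(m$acc, 0.5)
  expect_equal(m$prec, 0.5)
  expect_equal(m$rec, 0.5)
  # perfect separation
  mp <- ddi_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unlist(mp[, c("acc", "auc", "f1", "prec", "rec", "ap")]),
               rep(1, 6L), ignore_attr = TRUE)
  # anti-predictor
  ma <- ddi_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(ma$acc, 0)
  expect_equal(ma$auc, 0)
  # single-class labels: ranking metrics undefined
  ms <- ddi_metrics(c(1, 1), c(0.6, 0.7))
  expect_true(is.na(ms$auc) && is.na(ms$ap))
})

test_that("AUC and AP agree with scikit-learn on random data", {
  set.seed(19)
  labels <- rbinom(40L, 1L, 0.5)
  labels[1:2] <- c(0L, 1L)
  probs <- round(runif(40L), 2)  # duplicated scores exercise tie handling
  script <- '
import sys, json
from sklearn.metrics import roc_auc_score, average_precision_score
d = json.load(sys.stdin)
json.dump({"auc": roc_auc_score(d["y"], d["p"]),
           "ap": average_precision_score(d["y"], d["p"])}, sys.stdout)
'
  infile <- withr::local_tempfile()
  writeLines(jsonlite::toJSON(list(y = labels, p = probs)), infile)
  res <- system2("python", c("-c", shQuote(script)),
                 stdin = infile, stdout = TRUE, stderr = FALSE)
  ref <- jsonlite::fromJSON(paste(res, collapse = ""))
  m <- ddi_metrics(labels, probs)
  expect_equal(m$auc, ref$auc, tolerance = 1e-10)
  expect_equal(m$ap, ref$ap, tolerance = 1e-10)
})

test_that("negative sampling meets its contracts", {
  lib <- generate_library(30L, seed = 2L)
  tups <- generate_tuples(lib, n_per_relation = 8L, noise = 0, seed = 2L)
  pos <- tups[tups$label == 1L, c("drug_x", "drug_y", "relation")]
  neg <- sample_negatives(pos, lib$drug_id, seed = 5L)
  expect_identical(nrow(neg), nrow(pos))
  expect_true(all(neg$label == 0L))
  expect_true(all(neg$drug_x != neg$drug_y))
  key <- function(d) paste(d$drug_x, d$drug_y, d$relation)
  expect_length(intersect(key(neg), key(pos)), 0L)
  # exactly one drug replaced per tuple
  changed <- (neg$drug_x != pos$drug_x) + (neg$drug_y != pos$drug_y)
  expect_true(all(changed == 1L))
  # determinism under seed
  expect_identical(neg, sample_negatives(pos, lib$drug_id, seed = 5L))
  expect_false(identical(neg, sample_negatives(pos, lib$drug_id, seed = 6L)))
  expect_error(sample_negatives(pos, character(0)), "empty")
})

test_that("training reduces the loss and is reproducible under seed", {
  lib <- generate_library(40L, seed = 1L)
  tups <- generate_tuples(lib, n_per_relation = 10L, noise = 0, seed = 1L)
  cfg <- ddi_config(T = 2L, hidden = 8L, att_hidden = 6L, epochs = 8L,
                    batch_size = 64L, lr = 5e-3, seed = 11L)
  fit <- ddi_fit(tups, lib, cfg)
  expect_lt(utils::tail(fit$history$loss, 1L), fit$history$loss[1L])
  expect_equal(fit$history$lr, lr_schedule(5e-3, 0:7))
  fit2 <- ddi_fit(tups, lib, cfg)
  expect_equal(fit$params, fit2$params, tolerance = 1e-12)
  # input validation
  expect_error(ddi_fit(tups[0, ], lib, cfg), "no training tuples")
  bad <- tups; bad$drug_x[1] <- "NOPE"
  expect_error(ddi_fit(bad, lib, cfg), "absent from the drug table")
})

test_that("dropout masks regularize only when enabled", {
  cfg <- tiny_config()
  expect_null(molddi:::make_dropout_masks(cfg, 10L, 4L))
  cfgd <- tiny_config(dropout = 0.3)
  set.seed(1)
  m <- molddi:::make_dropout_masks(cfgd, 50L, 20L)
  expect_identical(dim(m$fs), c(50L, cfgd$hidden))
  expect_true(all(m$fs %in% c(0, 1 / 0.7)))
  # keep rate roughly honored
  expect_gt(mean(m$fs > 0), 0.5)
})

test_that("tidy, glance, predict, explain and checkpoints work end to end", {
  lib <- generate_library(30L, seed = 3L)
  tups <- generate_tuples(lib, n_per_relation = 6L, noise = 0, seed = 3L)
  cfg <- ddi_config(T = 2L, hidden = 6L, att_hidden = 4L, epochs = 3L,
                    batch_size = 64L, seed = 2L)
  fit <- ddi_fit(tups, lib, cfg)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(nrow(tidy(fit)), 3L)
  expect_identical(nrow(glance(fit)), 1L)
  pred <- predict(fit, tups)
  expect_true(all(pred$.prob > 0 & pred$.prob < 1))
  ev <- ddi_evaluate(fit, tups)
  expect_identical(ev$n, nrow(tups))
  ex <- ddi_explain(fit, tups[1:2, ])
  mu_sums <- tapply(ex$atoms$mu, paste(ex$atoms$pair, ex$atoms$role), sum)
  expect_equal(as.numeric(mu_sums), rep(1, 4L), tolerance = 1e-9)
  lam_sums <- tapply(ex$radii$lambda, paste(ex$radii$pair, ex$radii$role), sum)
  expect_equal(as.numeric(lam_sums), rep(1, 4L), tolerance = 1e-9)
  # ggplot constructors return plots without evaluation errors
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(ex), "ggplot")
  # checkpoint round trip preserves predictions exactly
  ck <- withr::local_tempfile(fileext = ".json")
  ddi_save(fit, ck)
  fit2 <- ddi_load(ck)
  pred2 <- predict(fit2, tups)
  expect_equal(pred2$.prob, pred$.prob, tolerance = 1e-12)
  # unknown inputs fail loudly
  expect_error(predict(fit, dplyr::mutate(tups[1, ], drug_x = "zz")),
               "unknown drug")
  expect_error(predict(fit, dplyr::mutate(tups[1, ], relation = 99L)),
               "unknown relation")
})
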