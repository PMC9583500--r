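# minimal decomposition/threshold builders for direct barcode-logic checks
fake_dec <- function(lam, labels = "all") {
  n <- nrow(lam)
  if (length(labels) == 1) labels <- rep(labels, n)
  structure(list(Lambda = cbind(reference = rep(1, n), lam),
                 K = ncol(lam), cell_ids = paste0("c", seq_len(n)),
                 sample_labels = labels),
            class = "csss_decomposition")
}
fake_thr <- function(lower, upper) {
  out <- data.frame(process = seq_along(lower), lower_cut = lower,
                    upper_cut = upper, method = "manual",
                    param = NA_real_, active_low = NA_real_,
                    active_high = NA_real_)
  class(out) <- c("csss_thresholds", "data.frame")
  out
}

test_that("barcodes encode tail membership with sign; binary mode is its absolute", {
  lam <- rbind(c(0.0, 0.0), c(3.0, 0.0), c(-3.0, 2.5), c(0.5, -2.5))
  dec <- fake_dec(lam)
  thr <- fake_thr(lower = c(-1, -1), upper = c(1, 1))
  b <- assign_barcodes(dec, thr)
  expect_equal(unname(b$barcodes),
               rbind(c(0L, 0L), c(1L, 0L), c(-1L, 1L), c(0L, -1L)))
  expect_equal(b$strings, c("00", "+0", "-+", "0-"))
  bb <- assign_barcodes(dec, thr, mode = "binary")
  expect_equal(unname(bb$barcodes), abs(unname(b$barcodes)))
  # boundary values are inactive (strictly outside the interval counts)
  dec2 <- fake_dec(rbind(c(1, -1)))
  expect_error(assign_barcodes(dec2, thr), NA)
})

test_that("threshold/decomposition process-count mismatch is a schema error", {
  dec <- fake_dec(matrix(0, 4, 3))
  expect_error(assign_barcodes(dec, fake_thr(-1, 1)), "K = 3")
})

test_that("cells planted with only one process get a barcode active only there", {
  spec <- small_scenario(seed = 21, n = 3000)
  sim <- generate_cells(spec)
  run <- run_pipeline(sim, out_dir = NULL)
  map <- match_planted_processes(run$decomposition, spec)
  p3 <- map[map$planted == "P3", ]
  b_cells <- sim$truth$subpop == "b"     # planted: process 3 only, induced
  bc <- run$barcodes$barcodes[b_cells, , drop = FALSE]
  active_pos <- bc[, p3$fitted_process] == sign(p3$cosine)
  expect_gt(mean(active_pos), 0.95)
  others <- bc[, -p3$fitted_process, drop = FALSE]
  expect_gt(mean(rowSums(others != 0) == 0), 0.95)
})

test_that("planted subpopulations are recovered with >= 90% diagonal mass", {
  spec <- rt_scenario_spec(seed = 22, n_cells = c(control = 5000, RT_d6 = 5000))
  sim <- generate_cells(spec)
  run <- run_pipeline(sim, out_dir = NULL)
  map <- match_planted_processes(run$decomposition, spec)
  planted_fit <- translate_barcodes(sim$truth$barcode, map,
                                    run$decomposition$K)
  expect_gt(mean(planted_fit == run$barcodes$strings), 0.9)
})

test_that("subpopulation tables count exactly and respect the dominance floor", {
  lam <- matrix(0, 10, 1)
  lam[1:4, 1] <- 3        # one barcode at 40%
  dec <- fake_dec(lam, labels = "only")
  thr <- fake_thr(-1, 1)
  tab <- tabulate_subpopulations(assign_barcodes(dec, thr))
  expect_equal(nrow(tab), 2L)
  expect_equal(sort(tab$frac_only), c(0.4, 0.6))
  expect_equal(sum(tab$count_only), 10L)
  expect_equal(tab$label[tab$barcode == "0"], "ss")
  expect_false(tab$dominant[tab$barcode == "0"])   # steady state never dominant
  expect_true(tab$dominant[tab$barcode == "+"])

  # sub-floor barcode retained but unflagged
  lam2 <- matrix(0, 1000, 1); lam2[1:5] <- 3       # 0.5% subpopulation
  tab2 <- tabulate_subpopulations(
    assign_barcodes(fake_dec(lam2, "only"), thr), abundance_floor = 0.01)
  row <- tab2[tab2$barcode == "+", ]
  expect_equal(row$count_only, 5L)
  expect_false(row$dominant)
})

test_that("fractions sum to one and counts to n per condition, conservation holds", {
  sim <- generate_cells(small_scenario(seed = 23, n = 1500))
  run <- run_pipeline(sim, out_dir = NULL)
  tab <- run$subpopulations
  for (cc in c("control", "RT_d6")) {
    expect_equal(sum(tab[[paste0("frac_", cc)]]), 1, tolerance = 1e-9)
    expect_equal(sum(tab[[paste0("count_", cc)]]),
                 sum(sim$expression$sample_labels == cc))
  }
})

test_that("the study scenario yields exactly eight dominant subpopulations", {
  sim <- generate_cells(small_scenario(seed = 24, n = 4000))
  run <- run_pipeline(sim, out_dir = NULL)
  expect_equal(sum(run$subpopulations$dominant), 8L)
})

test_that("labels follow descending pooled abundance with lexicographic ties", {
  lam <- matrix(0, 12, 2)
  lam[1:4, 1] <- 3      # "+0" x4
  lam[5:7, 2] <- 3      # "0+" x3
  lam[8:10, 1] <- -3    # "-0" x3 (ties with "0+": lexicographic order)
  bars <- assign_barcodes(fake_dec(lam, "x"), fake_thr(c(-1, -1), c(1, 1)))
  tab <- tabulate_subpopulations(bars)
  expect_equal(tab$label[tab$barcode == "+0"], "a")
  expect_equal(tab$label[tab$barcode == "-0"], "b")   # "-0" < "0+"
  expect_equal(tab$label[tab$barcode == "0+"], "c")
})

test_that("tabulation errors on an absent condition and is permutation-invariant", {
  sim <- generate_cells(small_scenario(seed = 25, n = 800))
  run <- run_pipeline(sim, out_dir = NULL)
  expect_error(tabulate_subpopulations(run$barcodes,
                                       conditions = c("control", "nope")),
               "empty condition: nope")
  b <- run$barcodes
  set.seed(1)
  perm <- sample(length(b$strings))
  bp <- b
  bp$strings <- b$strings[perm]
  bp$barcodes <- b$barcodes[perm, ]
  bp$sample_labels <- b$sample_labels[perm]
  bp$cell_ids <- b$cell_ids[perm]
  conds <- c("control", "RT_d6")
  t1 <- tabulate_subpopulations(b, conditions = conds)
  t2 <- tabulate_subpopulations(bp, conditions = conds)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("tightening thresholds weakly grows the all-zero barcode fraction", {
  sim <- generate_cells(small_scenario(seed = 26, n = 1000))
  dec <- fit_surprisal(sim$expression)
  zero <- strrep("0", dec$K)
  prev <- -1
  for (tf in c(0.25, 0.10, 0.02)) {
    thr <- compute_thresholds(dec, method = "quantile", tail_fraction = tf)
    frac0 <- mean(assign_barcodes(dec, thr)$strings == zero)
    expect_gte(frac0, prev)
    prev <- frac0
  }
})
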