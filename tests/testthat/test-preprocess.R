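test_that("case-control matching pairs by batch and bead keys", {
  ctl <- data.frame(sample_id = "c1", batch_id = "A", bead_id = "1")
  trt <- data.frame(sample_id = c("t1", "t2"), batch_id = "A", bead_id = "1",
                    drug_id = "d")
  out <- match_case_control(ctl, trt)
  expect_equal(nrow(out$pairs), 2)
  expect_equal(out$pairs$control_sample, c("c1", "c1"))
  # treatment in a batch with no control is reported unmatched
  trt2 <- data.frame(sample_id = "t3", batch_id = "B", bead_id = "1")
  out2 <- match_case_control(ctl, trt2)
  expect_equal(nrow(out2$pairs), 0)
  expect_equal(out2$unmatched$sample_id, "t3")
  # exhaustive oracle on a 5-control / 7-treatment toy manifest
  set.seed(41)
  ctl5 <- data.frame(sample_id = paste0("c", 1:5),
                     batch_id = sample(c("A", "B"), 5, TRUE),
                     bead_id = sample(1:2, 5, TRUE))
  trt7 <- data.frame(sample_id = paste0("t", 1:7),
                     batch_id = sample(c("A", "B", "C"), 7, TRUE),
                     bead_id = sample(1:2, 7, TRUE))
  out3 <- match_case_control(ctl5, trt7)
  brute <- sum(vapply(seq_len(7), function(i) {
    any(ctl5$batch_id == trt7$batch_id[i] & ctl5$bead_id == trt7$bead_id[i])
  }, logical(1)))
  expect_equal(nrow(out3$pairs), brute)
  expect_equal(nrow(out3$pairs) + nrow(out3$unmatched), 7)
  expect_error(match_case_control(ctl[, "sample_id", drop = FALSE], trt),
               "missing metadata")
  ctl_na <- ctl; ctl_na$bead_id <- NA
  expect_error(match_case_control(ctl_na, trt), "missing batch/bead")
})

test_that("pair correlation filter keeps rho > threshold and flags degenerates", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1)
  expect_true(filter_pairs_by_correlation(x, x)$keep)
  expect_false(filter_pairs_by_correlation(x, -x)$keep)
  # printed 6-gene toy pair against an independent Pearson computation
  a <- c(0.2, -1.1, 0.5, 2.0, -0.3, 0.8)
  b <- c(0.1, -0.9, 0.7, 1.5, -0.2, 1.2)
  res <- filter_pairs_by_correlation(matrix(a, 1), matrix(b, 1),
                                     threshold = 0.75)
  expect_equal(res$correlation, cor(a, b))
  expect_equal(res$keep, cor(a, b) > 0.75)
  # affine rescaling invariance of the decision
  res2 <- filter_pairs_by_correlation(matrix(3 * a + 1, 1),
                                      matrix(-0 * b + 2 * b - 5, 1))
  expect_equal(res2$correlation, res$correlation, tolerance = 1e-12)
  # degenerate profile is rejected with a reason, not an error
  res3 <- filter_pairs_by_correlation(matrix(rep(1, 6), 1), matrix(b, 1))
  expect_false(res3$keep)
  expect_equal(res3$reason, "degenerate")
})

test_that("per-gene standardization uses population variance and training rows only", {
  x <- matrix(c(1, 2, 3), 3, 1)
  colnames(x) <- "g1"
  st <- standardize_genes(x)
  expect_equal(as.numeric(st$matrix),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(st$transform$variance, "population")
  # constant gene: flagged, centered only
  xc <- cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  st2 <- standardize_genes(xc)
  expect_true(st2$transform$flagged["g2"])
  expect_equal(as.numeric(st2$matrix[, "g2"]), c(0, 0, 0))
  # new rows are transformed with the training statistics
  set.seed(42)
  xa <- matrix(rnorm(40), 8, 5,
               dimnames = list(NULL, paste0("g", 1:5)))
  st3 <- standardize_genes(xa, fit_on = 1:5)
  fit_rows <- st3$matrix[1:5, ]
  expect_lt(max(abs(colMeans(fit_rows))), 1e-10)
  expect_lt(max(abs(colMeans(fit_rows^2) - 1)), 1e-10)
  xnew <- matrix(rnorm(10), 2, 5, dimnames = list(NULL, paste0("g", 1:5)))
  manual <- sweep(sweep(xnew, 2, st3$transform$center), 2,
                  st3$transform$scale, "/")
  expect_equal(apply_gene_transform(st3$transform, xnew), manual)
  # gene-set provenance is enforced
  colnames(xnew) <- paste0("h", 1:5)
  expect_error(apply_gene_transform(st3$transform, xnew), "gene set")
  expect_error(standardize_genes(xa, fit_on = integer()), "nonempty")
})

test_that("first-PC removal deflates the leading axis and stores it for reuse", {
  # rank-1 matrix deflates to zero
  v <- c(1, 2, -1, 0.5)
  x1 <- outer(c(1, -2, 0.5, 3, -1), v)
  colnames(x1) <- paste0("g", 1:4)
  r1 <- remove_first_pc(x1)
  expect_lt(max(abs(r1$matrix)), 1e-8)
  # deflated training data have no variance along the component
  set.seed(43)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  x <- standardize_genes(x)$matrix
  r <- remove_first_pc(x)
  expect_lt(max(abs(r$matrix %*% r$transform$component)), 1e-8)
  # variance explained matches an independent eigendecomposition
  ev <- eigen(crossprod(x), symmetric = TRUE)$values
  expect_equal(r$transform$var_explained, ev[1] / sum(ev), tolerance = 1e-8)
  # idempotence with the stored component
  again <- apply_pc_removal(r$transform, r$matrix)
  expect_lt(max(abs(again - r$matrix)), 1e-10)
  # provenance on held-out data
  xnew <- matrix(rnorm(30), 3, 10, dimnames = list(NULL, paste0("h", 1:10)))
  expect_error(apply_pc_removal(r$transform, xnew), "gene set")
  expect_error(remove_first_pc(matrix(0, 3, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "rank-0")
})

test_that("waterfall binarization: median branch, elbow oracle, invariances", {
  # perfectly linear ramp: linearity branch, median cutoff
  ramp <- seq(0.9, 0.1, by = -0.1)
  wf <- waterfall_binarize(ramp)
  expect_equal(wf$branch, "median")
  expect_equal(wf$cutoff, median(ramp))
  expect_equal(unname(wf$labels), as.integer(ramp > median(ramp)))
  # elbow-shaped vector: cutoff at the brute-force max distance to the chord
  elbow <- c(0.9, 0.85, 0.8, 0.2, 0.15, 0.1)
  wf2 <- waterfall_binarize(elbow)
  expect_equal(wf2$branch, "elbow")
  s <- sort(elbow, decreasing = TRUE)
  n <- length(s)
  d <- vapply(seq_len(n), function(i) {
    # distance of point (i, s_i) to the chord (1, s_1)-(n, s_n)
    abs((s[n] - s[1]) * (i - 1) - (n - 1) * (s[i] - s[1])) /
      sqrt((n - 1)^2 + (s[n] - s[1])^2)
  }, numeric(1))
  expect_equal(wf2$cutoff, s[which.max(d)])
  expect_equal(unname(wf2$labels), as.integer(elbow > wf2$cutoff))
  # non-constant input gives a strictly interior sensitive fraction
  set.seed(44)
  for (k in 1:20) {
    aac <- round(runif(sample(5:15, 1)), 3)
    if (length(unique(aac)) < 3) next
    frac <- mean(waterfall_binarize(aac)$labels)
    expect_gt(frac, 0)
    expect_lt(frac, 1)
  }
  # invariance to input ordering and identifier re-indexing
  perm <- sample(length(elbow))
  wf3 <- waterfall_binarize(elbow[perm],
                            cell_line_id = paste0("cl", perm))
  expect_equal(wf3$cutoff, wf2$cutoff)
  expect_equal(unname(wf3$labels), unname(wf2$labels[perm]))
  expect_error(waterfall_binarize(c(0.1, 0.2)), "at least 3")
})

test_that("drug selection applies both coverage and prevalence criteria", {
  pairs <- data.frame(
    drug_id = c(rep("d1", 7), rep("d2", 20), rep("d3", 10)),
    cell_line_id = c(paste0("c", 1:7), paste0("c", 1:20), paste0("c", 1:10)))
  labels <- data.frame(
    drug_id = rep(c("d1", "d2", "d3"), each = 20),
    cell_line_id = rep(paste0("c", 1:20), 3),
    label = c(rbinom(20, 1, 0.5) * 0 + rep(c(1, 0), 10),   # 50% for d1
              c(rep(1, 2), rep(0, 18)),                     # 10% for d2
              c(rep(1, 8), rep(0, 12))))                    # 40% for d3
  sel <- select_drugs(pairs, labels)
  expect_false(sel$retained[sel$drug_id == "d1"])   # only 7 cell lines
  expect_false(sel$retained[sel$drug_id == "d2"])   # only 10% sensitive
  expect_true(sel$retained[sel$drug_id == "d3"])
  # brute-force evaluation of both predicates on a constructed cohort
  set.seed(45)
  drugs <- paste0("x", 1:5)
  pm <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(drug_id = d,
               cell_line_id = paste0("c", seq_len(sample(5:12, 1))))
  }))
  lb <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(drug_id = d, cell_line_id = paste0("c", 1:15),
               label = rbinom(15, 1, runif(1)))
  }))
  sel2 <- select_drugs(pm, lb)
  for (d in drugs) {
    ncl <- length(unique(pm$cell_line_id[pm$drug_id == d]))
    fr <- mean(lb$label[lb$drug_id == d])
    expect_equal(sel2$retained[sel2$drug_id == d], ncl >= 8 && fr >= 0.2)
  }
})

test_that("concentration selection takes the mode with low-tie break and log10 fallback", {
  expect_equal(most_common_concentration(c(1e-6, 1e-6, 1e-7)), 1e-6)
  expect_equal(most_common_concentration(c(1e-6, 1e-7)), 1e-7)  # tie: lower
  expect_equal(closest_concentration(1e-6, c(1e-8, 3e-7, 1e-4)), 3e-7)
})
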