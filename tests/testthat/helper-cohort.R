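# Toy labeled cohorts and split-plan invariant checks shared by the
# evaluation and acceptance tests.

make_cohort <- function(n_solo = 40, n_pair = 10, frac_pos = 0.3,
                        samples_per_cl = 1L) {
  cls <- c(sprintf("P%02d", seq_len(n_pair)),
           sprintf("S%02d", seq_len(n_solo)))
  labels <- c(rbinom(n_pair, 1, frac_pos),
              rep(c(1, 0), c(round(n_solo * frac_pos),
                             n_solo - round(n_solo * frac_pos))))
  do.call(rbind, lapply(seq_along(cls), function(i) {
    data.frame(sample_id = sprintf("%s_s%d", cls[i],
                                   seq_len(samples_per_cl)),
               cell_line_id = cls[i], label = labels[i])
  }))
}

check_split_invariants <- function(plan, singletons, pair_cls) {
  cl_of <- stats::setNames(as.character(singletons$cell_line_id),
                           singletons$sample_id)
  for (sp in plan$splits) {
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$val, sp$test), 0)
    expect_setequal(c(sp$train, sp$val, sp$test), singletons$sample_id)
    # no perturbation-source cell line ever reaches the test fold
    expect_length(intersect(cl_of[sp$test], pair_cls), 0)
    # grouping: all samples of one cell line share one role
    for (role in list(sp$train, sp$val, sp$test)) {
      other <- setdiff(singletons$sample_id, role)
      expect_length(intersect(cl_of[role], cl_of[other]), 0)
    }
    expect_setequal(c(sp$train_pair_cell_lines, sp$val_pair_cell_lines),
                    pair_cls)
  }
}
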