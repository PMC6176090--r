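mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query = r[[1]], subject = r[[2]], pident = 90, length = 100,
               evalue = as.numeric(r[[3]]), bitscore = as.numeric(r[[4]]))))
}

test_that("single passing hit yields its KO as best", {
  hits <- mk_hits(list("q1", "s1", 1e-10, 80))
  km <- data.frame(subject = "s1", ko = "K00001")
  asg <- assign_ko(hits, km)
  expect_equal(asg$assignments$ko, "K00001")
  expect_equal(asg$assignments$cum_score, 80)
  expect_true(asg$assignments$best)
})

test_that("the 90% retention rule keeps 91 vs 100 and drops 89.9 vs 100", {
  km <- data.frame(subject = c("s1", "s2", "s3"),
                   ko = c("K00001", "K00002", "K00003"))
  hits <- mk_hits(list("q1", "s1", 1e-10, 100),
                  list("q1", "s2", 1e-10, 91),
                  list("q1", "s3", 1e-10, 50))
  asg <- assign_ko(hits, km)
  expect_setequal(asg$assignments$ko, c("K00001", "K00002"))
  expect_equal(asg$assignments$ko[asg$assignments$best], "K00001")

  hits2 <- mk_hits(list("q1", "s1", 1e-10, 100),
                   list("q1", "s2", 1e-10, 89.9))
  expect_equal(assign_ko(hits2, km)$assignments$ko, "K00001")
})

test_that("e-value cutoff and unmapped subjects are applied and counted", {
  km <- data.frame(subject = "s1", ko = "K00001")
  hits <- mk_hits(list("q1", "s1", 1e-3, 500),   # fails e-value
                  list("q2", "sX", 1e-10, 80))   # unmapped subject
  asg <- assign_ko(hits, km)
  expect_equal(nrow(asg$assignments), 0)
  expect_equal(asg$n_unassigned, 2)
  expect_equal(asg$n_unmapped_subjects, 1)
})

test_that("assignment equals brute-force group-by-sum on random tables", {
  ht <- simulate_hit_table(300, 25, seed = 77)
  asg <- assign_ko(ht$hits, ht$ko_map)
  # brute-force: per query, retain KOs within 90% of the best cumulative
  for (q in unique(ht$truth$query)) {
    tr <- ht$truth[ht$truth$query == q, ]
    keep <- tr[tr$cum_score >= 0.9 * max(tr$cum_score), ]
    got <- asg$assignments[asg$assignments$query == q, ]
    expect_setequal(paste(got$ko, got$cum_score),
                    paste(keep$ko, keep$cum_score))
  }
  expect_setequal(unique(asg$assignments$query), unique(ht$truth$query))
})

make_urg_fixture <- function() {
  grid <- seq(0L, 36L, 6L)
  rt <- rbind(gA = c(10, 1, 1, 1, 1, 1, 1),
              gB = c(1, 8, 9, 1, 1, 1, 1),
              gC = c(1, 1, 1, 1, 2, 3, 12))
  colnames(rt) <- grid
  labels <- c(gA = "URG1", gB = "URG2", gC = "URG3")
  urg <- structure(list(labels = labels), class = "urg_assignment")
  profile <- structure(list(rpkm_time = rt), class = "expression_profile")
  list(urg = urg, profile = profile,
       partition = stage_partition(grid))
}

test_that("BRITE roll-up sums characteristic-stage RPKM per category", {
  fx <- make_urg_fixture()
  km <- data.frame(subject = "s1", ko = "K1")
  asg <- assign_ko(mk_hits(list("gA", "s1", 1e-10, 50)), km)
  bm <- data.frame(ko = "K1", levelA = "A", levelB = "B1")
  out <- brite_rollup(asg, bm, fx$urg, fx$profile, fx$partition)
  expect_equal(out$signal[out$urg == "URG1" & out$levelB == "B1"], 10)

  # a gene in two categories contributes its full RPKM to both
  bm2 <- rbind(bm, data.frame(ko = "K1", levelA = "A", levelB = "B2"))
  out2 <- brite_rollup(asg, bm2, fx$urg, fx$profile, fx$partition)
  expect_equal(sort(out2$signal), c(10, 10))

  # URG2/URG3 use their stage peaks
  asgB <- assign_ko(mk_hits(list("gB", "s1", 1e-10, 50),
                            list("gC", "s1", 1e-10, 50)), km)
  outB <- brite_rollup(asgB, bm, fx$urg, fx$profile, fx$partition)
  expect_equal(outB$signal[outB$urg == "URG2"], 9)   # max early
  expect_equal(outB$signal[outB$urg == "URG3"], 12)  # max late
  # timecourse_sum mode
  outS <- brite_rollup(asgB, bm, fx$urg, fx$profile, fx$partition,
                       rpkm_agg = "timecourse_sum")
  expect_equal(outS$signal[outS$urg == "URG2"], sum(fx$profile$rpkm_time["gB", ]))
})

test_that("KO without a BRITE path rolls up as unclassified; removal never increases signal", {
  fx <- make_urg_fixture()
  km <- data.frame(subject = c("s1", "s2"), ko = c("K1", "K2"))
  asg <- assign_ko(mk_hits(list("gA", "s1", 1e-10, 50),
                           list("gB", "s2", 1e-10, 50)), km)
  bm <- data.frame(ko = "K1", levelA = "A", levelB = "B1")
  out <- brite_rollup(asg, bm, fx$urg, fx$profile, fx$partition)
  expect_equal(out$levelB[out$urg == "URG2"], "unclassified")

  # removing a gene from the assignment never increases any signal
  asg_small <- asg
  asg_small$assignments <- asg$assignments[asg$assignments$query != "gA", ]
  out_small <- brite_rollup(asg_small, bm, fx$urg, fx$profile, fx$partition)
  for (i in seq_len(nrow(out_small))) {
    full <- out$signal[out$urg == out_small$urg[i] &
                         out$levelB == out_small$levelB[i]]
    expect_gte(full, out_small$signal[i])
  }
})
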