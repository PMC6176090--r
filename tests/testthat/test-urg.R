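# Small helper: build a contrast_set-shaped object and profile directly
# from a D specification so classifier logic can be exercised exactly.
manual_tables <- function(d_list, rpkm_rows, grid) {
  tn <- as.character(grid)
  k <- length(grid)
  ng <- length(rpkm_rows)
  lfc <- array(0, dim = c(ng, k, k), dimnames = list(names(rpkm_rows), tn, tn))
  sig <- array(FALSE, dim = dim(lfc), dimnames = dimnames(lfc))
  for (g in names(d_list)) for (key in names(d_list[[g]])) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    v <- d_list[[g]][[key]]
    lfc[g, ab[1], ab[2]] <- v; lfc[g, ab[2], ab[1]] <- -v
    sig[g, ab[1], ab[2]] <- sig[g, ab[2], ab[1]] <- v != 0
  }
  rpkm_time <- do.call(rbind, rpkm_rows)
  colnames(rpkm_time) <- tn
  list(contrasts = structure(list(lfc = lfc, sig = sig, time_points = grid,
                                  alpha = 1e-5, min_fold = 2),
                             class = "contrast_set"),
       profile = structure(list(rpkm_time = rpkm_time),
                           class = "expression_profile"))
}

grid7 <- seq(0L, 36L, 6L)
part7 <- stage_partition(grid7)

test_that("URG1 formula: direction, nonzero sum, strict RPKM maximum, floor", {
  others <- setdiff(grid7, 0)
  mk <- function(dvals, rpkm) {
    d <- setNames(as.list(dvals), paste0("0|", others))
    manual_tables(list(g1 = d), list(g1 = rpkm), grid7)
  }
  up1 <- c(10, rep(5, 6))          # T0 strictly maximal, floor passed
  # all contrasts down from T0 -> URG1
  t <- mk(rep(-2, 6), up1)
  expect_true(classify_urg1(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg1)
  # all-zero D fails the sum-nonzero clause
  t <- mk(rep(0, 6), up1)
  expect_false(classify_urg1(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg1)
  # a single positive D violates the intersection regardless of RPKM
  t <- mk(c(1.5, rep(-2, 5)), up1)
  expect_false(classify_urg1(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg1)
  # tied RPKM maximum is not strictly greater
  t <- mk(rep(-2, 6), c(10, 10, rep(5, 5)))
  expect_false(classify_urg1(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg1)
})

test_that("URG2 formula: early rise, late fall, sum, early RPKM peak", {
  mk <- function(d, rpkm) manual_tables(list(g1 = d), list(g1 = rpkm), grid7)
  keys_0e <- paste0("0|", c(6, 12, 18))
  keys_el <- as.vector(outer(c(6, 12, 18), c(24, 30, 36), paste, sep = "|"))
  rpkm_early_peak <- c(5, 20, 20, 20, 5, 5, 5)
  d_full <- c(setNames(as.list(rep(3, 3)), keys_0e),
              setNames(as.list(rep(-3, 9)), keys_el))
  t <- mk(d_full, rpkm_early_peak)
  expect_true(classify_urg2(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg2)
  # flat gene fails
  t <- mk(setNames(as.list(rep(0, 3)), keys_0e), rpkm_early_peak)
  expect_false(classify_urg2(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg2)
  # a late rise disqualifies even with early rise present
  d_bad <- d_full; d_bad[["6|24"]] <- 2
  t <- mk(d_bad, rpkm_early_peak)
  expect_false(classify_urg2(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg2)
  # all_early_max mode demands every early point beat every other
  rpkm_one_early <- c(7, 20, 6, 6, 5, 5, 5)
  t <- mk(d_full, rpkm_one_early)
  expect_true(classify_urg2(d_matrix(t$contrasts), t$profile$rpkm_time, part7,
                            rpkm_rule = "any_early_max")$urg2)
  expect_false(classify_urg2(d_matrix(t$contrasts), t$profile$rpkm_time, part7,
                             rpkm_rule = "all_early_max")$urg2)
})

test_that("URG3 formula holds on a monotone rising profile and fails on ties", {
  keys <- as.vector(outer(c(0, 6, 12, 18), c(24, 30, 36), paste, sep = "|"))
  mk <- function(d, rpkm) manual_tables(list(g1 = d), list(g1 = rpkm), grid7)
  t <- mk(setNames(as.list(rep(2, 12)), keys), c(5, 5, 6, 7, 20, 25, 30))
  expect_true(classify_urg3(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg3)
  t <- mk(setNames(as.list(rep(0, 12)), keys), c(5, 5, 6, 7, 20, 25, 30))
  expect_false(classify_urg3(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg3)
  # late maximum tied with an early point
  t <- mk(setNames(as.list(rep(2, 12)), keys), c(5, 30, 6, 7, 20, 25, 30))
  expect_false(classify_urg3(d_matrix(t$contrasts), t$profile$rpkm_time, part7)$urg3)
})

test_that("masking modes: significant-only zeroes, raw passes through", {
  tabs <- make_random_tables(99, 50, grid7)
  D_raw <- d_matrix(tabs$contrasts, "raw")
  expect_identical(D_raw, tabs$contrasts$lfc)
  D <- d_matrix(tabs$contrasts)
  expect_true(all(D[!tabs$contrasts$sig] == 0))
  expect_identical(D[tabs$contrasts$sig], tabs$contrasts$lfc[tabs$contrasts$sig])
})

test_that("assign matches the brute-force formula evaluator on random tables", {
  for (case in list(list(grid = grid7, early = c(6L, 12L, 18L)),
                    list(grid = c(seq(0L, 36L, 6L), 42L, 44L),
                         early = c(6L, 12L, 18L)))) {
    part <- stage_partition(case$grid, early = case$early)
    tabs <- make_random_tables(7, 300, case$grid)
    prof <- structure(list(rpkm_time = tabs$rpkm_time),
                      class = "expression_profile")
    got <- assign_urg(tabs$contrasts, prof, part)$labels
    want <- brute_force_urg(d_matrix(tabs$contrasts), tabs$rpkm_time,
                            part$t0, part$early, part$late)
    expect_identical(got, want)
  }
})

test_that("URG groups are disjoint and the floor is monotone", {
  tabs <- make_random_tables(31, 400, grid7)
  prof <- structure(list(rpkm_time = tabs$rpkm_time),
                    class = "expression_profile")
  asg4 <- assign_urg(tabs$contrasts, prof, part7, floor = 4)
  asg0 <- assign_urg(tabs$contrasts, prof, part7, floor = 0)
  # at most one label per gene is structural (assign_urg errors otherwise);
  # relaxing the floor never removes a gene from a group
  labelled4 <- asg4$labels != "none"
  expect_true(all(asg0$labels[labelled4] == asg4$labels[labelled4]))
  expect_gte(sum(asg0$labels != "none"), sum(labelled4))
  # every labelled gene passed the floor
  expect_true(all(asg4$trace$floor_ok[labelled4]))
})

test_that("tightening alpha shrinks the masked D support pointwise", {
  sim <- simulate_counts(sim_config(n_genes = 300, effect_size = 4,
                                    dispersion = 0.1, bad_replicate_rate = 0,
                                    seed = 17))
  strict <- build_contrast_set(sim$cm, alpha = 1e-8)
  loose <- build_contrast_set(sim$cm, alpha = 1e-3)
  expect_true(all(!strict$sig | loose$sig))
  Ds <- d_matrix(strict); Dl <- d_matrix(loose)
  expect_true(all(Dl[Ds != 0] == Ds[Ds != 0]))
})

test_that("null data yields no URG assignments", {
  sim <- simulate_counts(sim_config(n_genes = 300, effect_size = 1,
                                    bad_replicate_rate = 0, seed = 19))
  prof <- rpkm(sim$cm, setNames(sim$lengths$length_bp, sim$lengths$gene_id))
  ctr <- build_contrast_set(sim$cm)
  asg <- assign_urg(ctr, prof, part7)
  expect_true(all(asg$labels == "none"))
})
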