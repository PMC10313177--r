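## independent brute-force scorer used as the oracle for the subgroup and
## ranking machinery (plain loops, no shared code)
brute_best <- function(values, responder, metric, n_cut = 8, min_size = 20) {
  ids <- names(values)[!is.na(values)]
  v <- values[ids]
  if (length(unique(v)) < 2) return(NULL)
  cuts <- seq(min(v), max(v), length.out = n_cut + 2)[seq_len(n_cut) + 1]
  best <- NULL
  for (ct in cuts) for (dir in c("above", "below")) {
    m <- if (dir == "above") ids[v >= ct] else ids[v < ct]
    if (length(m) < min_size) next
    val <- if (metric == "rp") mean(responder[m]) else
      sum(responder[m]) / sum(responder) -
        sum(!responder[m]) / sum(!responder)
    if (is.null(best) || val > best$value ||
        (val == best$value && length(m) > best$n))
      best <- list(value = val, n = length(m), direction = dir,
                   threshold = ct)
  }
  best
}

test_that("diversity indices reproduce direct summation", {
  d <- diversity(c(100, 0, 0, 0, 0))
  expect_equal(d$richness, 1L)
  expect_equal(d$shannon, 0)
  expect_true(is.na(d$evenness))
  d5 <- diversity(rep(100, 5))
  expect_equal(d5$shannon, log(5))
  expect_equal(d5$evenness, 1)
  # p = (1/2, 1/4, 1/4): H = 1.5 ln 2
  d3 <- diversity(c(200, 100, 100))
  expect_equal(d3$shannon, 1.5 * log(2))
  z <- diversity(c(0, 0))
  expect_equal(z$richness, 0L)
  expect_equal(z$shannon, 0)
  # extinction threshold: sub-cell residues do not count
  expect_equal(diversity(c(100, 0.5))$richness, 1L)
})

test_that("response probability and RIS obey their defining identities", {
  resp <- stats::setNames(rep(c(TRUE, FALSE), c(100, 100)),
                          sprintf("p%03d", 1:200))
  ids <- names(resp)
  expect_equal(response_probability(ids[1:50], resp), 1)
  expect_equal(response_probability(ids[101:150], resp), 0)
  expect_equal(response_probability(ids[c(1:43, 101:107)], resp), 0.86)
  expect_error(response_probability(character(0), resp), "empty")
  # full cohort scores zero; the exact responder set scores one
  expect_equal(ris(ids, resp), 0)
  expect_equal(ris(ids[1:100], resp), 1)
  # 72% of responders and 29% of nonresponders: 0.43
  expect_equal(ris(ids[c(1:72, 101:129)], resp), 0.43)
  all_resp <- stats::setNames(rep(TRUE, 5), letters[1:5])
  expect_error(ris(letters[1:2], all_resp), "undefined")
})

test_that("subgroups are uniformly spaced, filtered and enumerable", {
  set.seed(31)
  v <- stats::setNames(stats::runif(1000), sprintf("p%04d", 1:1000))
  sg <- make_subgroups(v, n_thresholds = 8, min_size = 20)
  # dense uniform values with interior cutoffs: all 16 direction x
  # cutoff subgroups survive the size filter
  expect_equal(length(sg), 16)
  thr <- sort(unique(sapply(sg, `[[`, "threshold")))
  expect_equal(diff(thr), rep(diff(thr)[1], 7), tolerance = 1e-9)
  # min_size larger than n: nothing survives
  expect_equal(make_subgroups(v[1:10], min_size = 20), list())
  # constant candidate: skipped
  expect_equal(make_subgroups(stats::setNames(rep(1, 100),
                                              sprintf("c%03d", 1:100))),
               list())
})

test_that("single-candidate ranking agrees with the brute-force oracle", {
  tab <- synthetic_table(n = 60, seed = 17, k = 3)
  resp <- stats::setNames(tab$responder, tab$id)
  for (metric in c("rp", "ris")) {
    rk <- rank_candidates(tab, metric, min_size = 20, n_boot = 0)
    for (cand in paste0("x", 1:3)) {
      want <- brute_best(stats::setNames(tab[[cand]], tab$id), resp,
                         metric)
      row <- rk[rk$candidate == cand, ]
      expect_equal(row$value, want$value, label = paste(metric, cand))
      expect_equal(row$n, want$n)
      expect_equal(row$direction, want$direction)
      expect_equal(row$threshold, want$threshold)
    }
    expect_false(is.unsorted(rev(rk$value)))
  }
})

test_that("pair ranking agrees with an exhaustive conjunction scan", {
  tab <- synthetic_table(n = 60, seed = 23, k = 3)
  resp <- stats::setNames(tab$responder, tab$id)
  pk <- rank_pairs(tab, "rp", min_size = 20)
  # oracle for one pair
  brute_pair <- function(c1, c2) {
    v1 <- stats::setNames(tab[[c1]], tab$id)
    v2 <- stats::setNames(tab[[c2]], tab$id)
    best <- -Inf
    for (t1 in seq(min(v1), max(v1), length.out = 10)[2:9])
      for (d1 in c(TRUE, FALSE))
        for (t2 in seq(min(v2), max(v2), length.out = 10)[2:9])
          for (d2 in c(TRUE, FALSE)) {
            m <- names(v1)[(if (d1) v1 >= t1 else v1 < t1) &
                             (if (d2) v2 >= t2 else v2 < t2)]
            if (length(m) < 20) next
            best <- max(best, mean(resp[m]))
          }
    best
  }
  for (i in seq_len(nrow(pk))) {
    expect_equal(pk$value[i], brute_pair(pk$candidate_1[i],
                                         pk$candidate_2[i]))
  }
  # a pair of identical candidates never scores below the single
  # candidate: same-direction conjunctions reproduce every single
  # threshold, and opposite-direction conjunctions add band subgroups
  tab2 <- tab
  tab2$x2 <- tab2$x1
  s <- rank_candidates(tab2, "rp", min_size = 20, n_boot = 0)
  p2 <- rank_pairs(tab2, "rp", min_size = 20, candidates = c("x1", "x2"))
  expect_gte(p2$value[1], s$value[s$candidate == "x1"])
})

test_that("metrics are invariant to patient order and affine relabeling", {
  tab <- synthetic_table(n = 80, seed = 3, k = 2)
  rk <- rank_candidates(tab, "ris", min_size = 20, n_boot = 0)
  perm <- tab[sample.int(nrow(tab)), ]
  rk2 <- rank_candidates(perm, "ris", min_size = 20, n_boot = 0)
  expect_equal(rk$value, rk2$value)
  expect_equal(rk$candidate, rk2$candidate)
  # affine transform: same memberships under uniform threshold spacing
  tab3 <- tab
  tab3$x1 <- 5 + 3 * tab3$x1
  rk3 <- rank_candidates(tab3, "ris", min_size = 20, n_boot = 0)
  expect_equal(rk3$value[rk3$candidate == "x1"],
               rk$value[rk$candidate == "x1"])
  expect_equal(rk3$n[rk3$candidate == "x1"], rk$n[rk$candidate == "x1"])
})

test_that("bootstrap confidence intervals are seed-deterministic", {
  tab <- synthetic_table(n = 60, seed = 8, k = 2)
  a <- rank_candidates(tab, "rp", n_boot = 100, seed = 42)
  b <- rank_candidates(tab, "rp", n_boot = 100, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$ci_low <= a$ci_high))
})

test_that("a noisy threshold driver is recovered as the top candidate", {
  hits <- 0
  for (s in 1:20) {
    tab <- synthetic_table(n = 200, seed = 100 + s, noise = 0.1, k = 4)
    rk <- rank_candidates(tab, "rp", min_size = 20, n_boot = 0)
    hits <- hits + (rk$candidate[1] == "x1")
  }
  expect_gt(hits / 20, 0.95)
})

test_that("candidate extraction matches independent recomputation", {
  fx <- fast_fixture()
  tab <- fx$table
  p <- fx$cohort[[1]]
  les <- setdiff(baseline_lesions(p), "tumor_primary")
  y <- p$baseline_state
  til <- sapply(les, function(tc) {
    tcyt <- sum(y[paste0(tc, ".tcyt.", 1:8)])
    tils <- tcyt + y[[paste0(tc, ".tcyt_exhausted")]] +
      y[[paste0(tc, ".th")]] + y[[paste0(tc, ".treg")]]
    allc <- sum(y[paste0(tc, ".cancer.", 1:5)]) + tils +
      y[[paste0(tc, ".m1")]] + y[[paste0(tc, ".m2")]] +
      y[[paste0(tc, ".mdsc")]] + y[[paste0(tc, ".apc_immature")]] +
      y[[paste0(tc, ".apc_mature")]]
    tils / allc
  })
  expect_equal(tab$frac_til[tab$id == p$id], mean(til), tolerance = 1e-12)
  expect_equal(nrow(tab), length(fx$cohort))
})
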