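mc2 <- make_modcat(2L)  # enzymes E_<attr>_1, E_<attr>_2

test_that("potency counts chemical-protein interaction pairs", {
  cat <- make_catalog(c("M1", "M2", "M3"),
                      chemicals = list("C1", c("C2", "C3"), "C4"))
  inter <- data.frame(
    chemical_id = c("C1", "C1", "C2", "C3"),
    protein_id = c("E_HAT_1", "E_HAT_2", "E_DNMT_1", "E_DNMT_1"),
    action = c("activation", "inhibition", "unspecified", "inhibition"),
    stringsAsFactors = FALSE)
  prof <- build_potency_profiles(cat, inter, mc2)
  # one chemical hitting two HAT enzymes: two pairs
  expect_equal(unname(prof$pairs["M1", "HAT"]), 2L)
  # two chemicals hitting the same enzyme: still two pairs
  expect_equal(unname(prof$pairs["M2", "DNMT"]), 2L)
  # no matching interaction: all-zero profile
  expect_true(all(prof$pairs["M3", ] == 0))
  # unspecified is tallied as inhibiting
  expect_equal(unname(prof$inhibiting["M2", "DNMT"]), 2L)
  expect_equal(prof$pairs, prof$activating + prof$inhibiting)
})

test_that("histone-modifying status requires any touched attribute", {
  A <- attr_matrix(c("M1", "M2", "M3")); I <- attr_matrix(c("M1", "M2", "M3"))
  I["M2", "DNMT"] <- 1L
  A["M3", "ATP"] <- 1L
  prof <- make_profiles(A, I)
  expect_equal(unname(is_histone_modifying(prof)), c(FALSE, TRUE, TRUE))
})

test_that("chromatin calls follow the net heterochromatic-minus-euchromatic rule", {
  ids <- c("cond", "pois", "atp_only", "none")
  A <- attr_matrix(ids); I <- attr_matrix(ids)
  # 3 heterochromatic attributes and 1 euchromatic touched -> net +2
  A["cond", c("DNMT", "H3K9", "H4K20")] <- 1L
  A["cond", "HAT"] <- 1L
  # 2 het + 2 eu -> poising
  A["pois", c("HDAC", "H3K27")] <- 1L
  A["pois", c("H3K4", "H3S10")] <- 1L
  A["atp_only", "ATP"] <- 5L
  calls <- chromatin_call(make_profiles(A, I), mc2)
  expect_equal(calls$label, c("condensing", "poising", "poising",
                              "non_modifying"))
  expect_equal(calls$all_net[1L], 2)
  expect_equal(calls$all_net[3L], 0)  # ambivalent ATP contributes nothing
  # per-class tallies restrict to the chemistry classes
  expect_equal(calls$ac_het[2L], 1)  # HDAC
  expect_equal(calls$ph_eu[2L], 1)   # H3S10
  expect_equal(calls$me_net[1L], 3)  # DNMT + H3K9 + H4K20 het, no me eu
})

test_that("count-mode calls ignore action labels; direction_aware flips inhibitions", {
  ids <- "M1"
  A <- attr_matrix(ids); I <- attr_matrix(ids)
  I["M1", "HDAC"] <- 3L  # inhibiting a heterochromatic mark
  prof <- make_profiles(A, I)
  cnt <- chromatin_call(prof, mc2, direction = "count")
  expect_equal(cnt$label, "condensing")
  dir <- chromatin_call(prof, mc2, direction = "direction_aware")
  expect_equal(dir$label, "unpacking")
  # flipping every inhibition to activation changes nothing in count mode
  prof2 <- make_profiles(I, A)
  expect_equal(chromatin_call(prof2, mc2, direction = "count")$all_net,
               cnt$all_net)
})

test_that("adding heterochromatic pairs never decreases the net score", {
  set.seed(21)
  for (i in 1:10) {
    gran <- sample(c("distinct_modifications", "interaction_pairs"), 1L)
    A <- attr_matrix("M1"); I <- attr_matrix("M1")
    A["M1", ] <- rpois(18, 0.7)
    base <- chromatin_call(make_profiles(A, I), mc2, granularity = gran)
    A2 <- A; A2["M1", "H3K9"] <- A2["M1", "H3K9"] + 1L
    more <- chromatin_call(make_profiles(A2, I), mc2, granularity = gran)
    expect_gte(more$all_net, base$all_net)
  }
})

test_that("correlation screen recovers exact relations and respects guards", {
  ids <- sprintf("M%02d", 1:10)
  A <- attr_matrix(ids); I <- attr_matrix(ids)
  A[, "H3K9"] <- 1:10  # all modifying
  prof <- make_profiles(A, I)
  scores <- data.frame(medicinal_id = ids, cold_hot = 1:10,
                       flavor = NA_real_, yinyang = 1:10)
  res <- correlate_scores_with_potency(scores, prof, "H3K9", "cold_hot")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-12)
  expect_equal(res$n, 10L)
  expect_error(correlate_scores_with_potency(scores, prof, "HAT", "cold_hot"),
               "variance")
  screen <- correlation_screen(scores, prof, "cold_hot")
  expect_equal(nrow(screen), 18L)
  expect_true(screen$significant[screen$attribute == "H3K9"])
  expect_true(all(is.na(screen$r[screen$attribute == "HAT"])))
})

test_that("independent scores and potencies rarely appear correlated", {
  n <- 1000L
  ids <- sprintf("M%04d", seq_len(n))
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    A <- attr_matrix(ids); I <- attr_matrix(ids)
    A[, "H3K9"] <- stats::rpois(n, 2) + 1L  # keep everyone modifying
    prof <- make_profiles(A, I)
    scores <- data.frame(medicinal_id = ids,
                         cold_hot = sample(-3:3, n, replace = TRUE),
                         flavor = 0, yinyang = 0)
    abs(correlate_scores_with_potency(scores, prof, "H3K9", "cold_hot")$r)
  }, 0)
  expect_gte(mean(hits < 0.1), 0.95)
})

test_that("materia medica summary partitions the modifying medicinals", {
  ids <- c("a", "b", "c", "d")
  A <- attr_matrix(ids); I <- attr_matrix(ids)
  A["b", c("DNMT", "H3K9")] <- 1L             # condensing
  A["c", c("H3K4", "H3K36")] <- 1L            # unpacking
  A["d", c("DNMT", "H3K4")] <- 1L             # poising
  calls <- chromatin_call(make_profiles(A, I), mc2)
  s <- materia_medica_summary(calls)
  expect_equal(s$frac_modifying, 0.75)
  expect_equal(unname(s$class_fractions), rep(1 / 3, 3))
  expect_equal(sum(s$class_fractions) * s$n_modifying, s$n_modifying)

  none <- chromatin_call(make_profiles(attr_matrix(ids), attr_matrix(ids)),
                         mc2)
  s0 <- materia_medica_summary(none)
  expect_equal(s0$frac_modifying, 0)
  expect_true(all(is.na(s0$class_fractions)))
  expect_error(materia_medica_summary(calls[0, ]), "empty")
})
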