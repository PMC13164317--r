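test_that("ppidr uses a strict 0.5 cutoff and the documented class bounds", {
  expect_equal(ppidr(rep(0, 10))$ppidr, 0)
  expect_equal(ppidr(rep(0, 10))$disorder_class, "highly ordered")
  # scores exactly at 0.5 do not count as disordered
  expect_equal(ppidr(rep(0.5, 10))$ppidr, 0)
  d <- ppidr(c(rep(0.9, 4), rep(0.1, 6)))
  expect_equal(d$ppidr, 40)
  expect_equal(d$disorder_class, "highly disordered")
  # 10% and 30% land in the middle class
  expect_equal(ppidr(c(rep(0.9, 1), rep(0, 9)))$disorder_class, "moderately disordered")
  expect_equal(ppidr(c(rep(0.9, 3), rep(0, 7)))$disorder_class, "moderately disordered")
  expect_error(ppidr(numeric()), class = "nbhub_format_error")
  # permutation invariance
  withr::local_seed(6)
  tr <- stats::runif(50)
  expect_equal(ppidr(tr), ppidr(sample(tr)))
})

test_that("LLPS consensus labels honor every threshold convention", {
  expect_equal(llps_consensus(pspredictor = 0.7, fuzdrop = 0.8)$combined_label, "LLPS")
  expect_equal(llps_consensus(pspredictor = 0.7, fuzdrop = 0.3)$combined_label, "controversial")
  expect_equal(llps_consensus(pspredictor = 0.2, fuzdrop = 0.8)$combined_label, "controversial")
  expect_equal(llps_consensus(pspredictor = 0.2, fuzdrop = 0.3)$combined_label, "non-LLPS")
  # strict boundaries: exactly at threshold fails
  expect_equal(llps_consensus(catgranule = 0.5)$catgranule_label, "non-LLPS")
  expect_equal(llps_consensus(catgranule = 0.5 + 1e-9)$catgranule_label, "LLPS")
  expect_equal(llps_consensus(psphunter = 0.61)$psphunter_label, "unlikely")
  expect_equal(llps_consensus(psphunter = 0.36)$psphunter_label, "unlikely")
  expect_equal(llps_consensus(psphunter = 0.62)$psphunter_label, "likely")
  expect_equal(llps_consensus(psphunter = 0.35)$psphunter_label, "non-LLPS")
  # missing scores are unknown, never defaulted
  cc <- llps_consensus()
  expect_equal(cc$catgranule_label, "unknown")
  expect_equal(cc$combined_label, "unknown")
})

test_that("driver/client role uses inclusive 0.60 and run-length regions", {
  expect_equal(llps_role(0.60, NULL), "driver") # inclusive boundary
  expect_equal(llps_role(0.599, rep(0, 20)), "neither")
  track <- c(rep(0.1, 5), rep(0.7, 12), rep(0.1, 5))
  expect_equal(llps_role(0.4, track, min_region_length = 10), "client")
  expect_equal(llps_role(0.4, track, min_region_length = 13), "neither")
  # run structure matters: the same values scattered lose the region
  withr::local_seed(9)
  expect_equal(llps_role(0.4, sample(track), min_region_length = 12), "neither")
  # pDP exactly at 0.60 counts toward a region (inclusive)
  expect_equal(llps_role(0.4, rep(0.60, 10), min_region_length = 10), "client")
  expect_equal(llps_role(NA), "unknown")
})

test_that("gravy matches Kyte-Doolittle closed forms and flags bad residues", {
  expect_equal(gravy("GGGG"), -0.4)
  expect_equal(gravy("III"), 4.5)
  expect_equal(gravy("ACDE"), (1.8 + 2.5 - 3.5 - 3.5) / 4)
  expect_error(gravy("ACXE"), "position 3", class = "nbhub_format_error")
  # concatenation: length-weighted mean of parts
  withr::local_seed(10)
  aa <- names(kyte_doolittle)
  s1 <- paste(sample(aa, 12, TRUE), collapse = "")
  s2 <- paste(sample(aa, 30, TRUE), collapse = "")
  expect_equal(
    gravy(paste0(s1, s2)),
    (12 * gravy(s1) + 30 * gravy(s2)) / 42
  )
})

test_that("charge at pH follows Henderson-Hasselbalch and is monotone", {
  # lysine peptide at pH 1: N-terminus and side chain protonated,
  # C-terminus mostly neutral
  chg <- charge_at_ph("K", 1)
  expect_equal(chg,
    1 / (1 + 10^(1 - 7.5)) + 1 / (1 + 10^(1 - 10)) - 1 / (1 + 10^(3.55 - 1))
  )
  expect_gt(chg, 1.95)
  withr::local_seed(15)
  seq <- paste(sample(names(kyte_doolittle), 40, TRUE), collapse = "")
  phs <- seq(0, 14, by = 0.5)
  charges <- vapply(phs, function(p) charge_at_ph(seq, p), numeric(1))
  expect_false(is.unsorted(rev(charges)))
  # charge vanishes at the numerically solved isoelectric point
  pi_root <- stats::uniroot(function(p) charge_at_ph(seq, p), c(0, 14),
    tol = 1e-10
  )$root
  expect_lt(abs(charge_at_ph(seq, pi_root)), 1e-6)
  expect_equal(isoelectric_point(seq), pi_root, tolerance = 1e-6)
})

test_that("annotation rows are all-unknown when inputs are missing", {
  ann <- annotate_hubs(c("P1", "P2"))
  expect_equal(ann$combined_label, c("unknown", "unknown"))
  expect_equal(ann$disorder_class, c("unknown", "unknown"))
  expect_true(all(is.na(ann$ppidr)))
  g <- glance(ann)
  expect_equal(g$n_llps_combined, 0L)
  expect_equal(g$n_ptm_unknown, 2L)
})

test_that("annotation summary counts equal the generator ledger", {
  spec <- synthetic_spec(seed = 77, n_planted_hubs = 40)
  proteins <- sprintf("P%04d", 1:40)
  ts <- gen_tracks_and_scores(spec, proteins)
  ann <- annotate_hubs(
    proteins,
    scores = ts$scores, tracks = ts$tracks, ptm = ts$ptm,
    sequences = ts$sequences, min_region_length = spec$min_region_length
  )
  led <- ts$ledger
  expect_equal(ann$catgranule_label, led$catgranule_label)
  expect_equal(ann$psphunter_label, led$psphunter_label)
  expect_equal(ann$combined_label, led$combined_label)
  expect_equal(ann$role_label, led$role_label)
  expect_equal(ann$disorder_class, led$disorder_class)
  expect_identical(ann$sumo, led$sumo)
  expect_s3_class(autoplot(ann), "ggplot")
})
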