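test_that("aggregate allele frequency is additive over variants", {
  tab <- toyTable(toyRecord("v1", ac = 200, an = 2000),
                  toyRecord("v2", ac = 200, an = 2000))
  af <- aggregateAlleleFrequency(tab)
  expect_equal(af$q, 0.2)
  expect_equal(unname(af$perVariantQ), c(0.1, 0.1))
  expect_equal(names(af$perVariantQ), c("v1", "v2"))

  expect_equal(aggregateAlleleFrequency(toyTable(toyRecord("z", ac = 0)))$q,
               0)
  empty <- aggregateAlleleFrequency(records(tab)[0, ])
  expect_equal(empty$q, 0)
  expect_length(empty$perVariantQ, 0)

  expect_warning(
    aggregateAlleleFrequency(toyTable(toyRecord("v1", ac = 1200, an = 2000),
                                      toyRecord("v2", ac = 1800, an = 2000))),
    "exceeds 1")
  expect_error(
    aggregateAlleleFrequency(toyTable(toyRecord("v1"), toyRecord("v1"))),
    "once per stratum")
})

test_that("HWE component formulas behave at the boundaries", {
  expect_equal(hetPrevalence(0), 0)
  expect_equal(hetPrevalence(0.5), 0.5)  # maximum of 2pq
  expect_equal(homInclCompoundPrevalence(1), 1)
  expect_equal(homInclCompoundPrevalence(0.2), 0.04)
  expect_equal(homPrevalence(c(0.1, 0.1)), 0.02)
  expect_equal(homPrevalence(numeric(0)), 0)
  expect_equal(compoundHetPrevalence(0.2, c(0.1, 0.1)), 0.02)
  # single variant: no compound heterozygosity possible
  expect_equal(compoundHetPrevalence(0.1, 0.1), 0)
  expect_error(compoundHetPrevalence(0.3, c(0.1, 0.1)), "tolerance")
})

test_that("formulas agree exactly with ordered-pair enumeration", {
  cases <- list(c(1 / 3), c(0.1, 0.1), c(0.3, 0.2),
                c(1 / 7, 2 / 7, 3 / 7),
                c(0.01, 0.002, 0.0003, 0.00004))
  for (qi in cases) {
    q <- sum(qi)
    oracle <- enumPairPrevalence(qi)
    expect_equal(hetPrevalence(q), oracle$het, tolerance = 1e-12)
    expect_equal(homPrevalence(qi), oracle$hom, tolerance = 1e-12)
    expect_equal(compoundHetPrevalence(q, qi), oracle$compound,
                 tolerance = 1e-12)
    expect_equal(homInclCompoundPrevalence(q),
                 oracle$hom + oracle$compound, tolerance = 1e-12)
    # Eq-1 conservation
    expect_equal((1 - q)^2 + hetPrevalence(q) +
                   homInclCompoundPrevalence(q), 1, tolerance = 1e-12)
  }
})

test_that("compound-het prevalence is non-negative for random qi", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    qi <- runif(k, 0, 1 / k)
    expect_gte(compoundHetPrevalence(sum(qi), qi), 0)
  }
  # equality iff at most one variant has positive frequency
  expect_equal(compoundHetPrevalence(0.2, c(0.2, 0, 0)), 0)
})

test_that("estimatePrevalence composes components and tallies carriers", {
  tab <- toyTable(
    do.call(toyRecord, c(list("p1"), damagingProfile(3),
                         list(ac = 6, an = 2000, nhom = 1))),
    do.call(toyRecord, c(list("p2"), damagingProfile(2),
                         list(ac = 4, an = 2000))),
    do.call(toyRecord, c(list("b1"), damagingProfile(1),
                         list(ac = 100, an = 2000))))
  est <- estimatePrevalence(tab, PathogenicityDefinition(minTools = 2))
  expect_equal(est@nVariants, 2L)
  expect_equal(est@sampleSize, 1000)
  expect_equal(est@q, 10 / 2000)
  expect_equal(est@pHet, 2 * (1 - 0.005) * 0.005)
  expect_equal(est@pHom, (6 / 2000)^2 + (4 / 2000)^2)
  expect_equal(est@pCh, est@q^2 - est@pHom)
  expect_equal(est@observedHetCarriers, 6 - 2 + 4)
  expect_equal(est@observedHomCarriers, 1)
  expect_true(validObject(est))

  # doubling q scales het ~x2 and hom x4
  tab2 <- VariantTable(within(records(tab), ac <- ac * 2))
  est2 <- estimatePrevalence(tab2, PathogenicityDefinition(minTools = 2))
  expect_equal(est2@pHomInclCh / est@pHomInclCh, 4)
  expect_equal(est2@pHet / est@pHet, 2 * (1 - est2@q) / (1 - est@q))
})

test_that("zero pathogenic variants yield NA estimates, not zero", {
  tab <- toyTable(do.call(toyRecord, c(list("b1"), damagingProfile(1))))
  est <- estimatePrevalence(tab, PathogenicityDefinition(minTools = 2))
  expect_equal(est@nVariants, 0L)
  expect_true(is.na(est@pHet))
  expect_true(is.na(est@pHomInclCh))
  # absent stratum behaves the same
  est2 <- estimatePrevalence(tab, PathogenicityDefinition(minTools = 2),
                             population = "fin")
  expect_true(is.na(est2@q))
})

test_that("threshold sweep is monotone and ordered by k", {
  tab <- readVariantTable(lepFixturePath())
  sweep <- thresholdSweep(tab, kValues = c(3, 0, 2, 1, 5))
  expect_equal(names(sweep), c("k0", "k1", "k2", "k3", "k5"))
  qs <- vapply(sweep, function(e) e@q, numeric(1))
  expect_true(all(diff(qs) <= 0))
  het <- vapply(sweep, function(e) e@pHet, numeric(1))
  expect_true(all(diff(het) <= 0))
  nv <- vapply(sweep, function(e) e@nVariants, integer(1))
  expect_true(all(diff(nv) <= 0))
})

test_that("occurrence rate is the size-corrected variant count", {
  expect_equal(signif(occurrenceRate(8, 3614), 2), 0.0022)
  expect_equal(signif(occurrenceRate(13, 12487), 3), 0.00104)
  expect_equal(occurrenceRate(0, 1000), 0)
  expect_error(occurrenceRate(1, 0))
})

test_that("ratio formatting follows the requested rounding mode", {
  expect_equal(formatPrevalenceRatio(1.6246e-3, "integer"), "1: 616")
  expect_equal(formatPrevalenceRatio(4.7353e-4, "sigfigs", 2), "1: 2,100")
  expect_equal(formatPrevalenceRatio(1, "integer"), "1: 1")
  expect_equal(formatPrevalenceRatio(5.6085e-8, "sigfigs", 4),
               "1: 17,830,000")
  # paper mode: integers below 1,000, else 3 significant figures
  expect_equal(formatPrevalenceRatio(1 / 616, "paper"), "1: 616")
  expect_equal(formatPrevalenceRatio(1 / 1513036, "paper"), "1: 1,510,000")
  expect_equal(formatPrevalenceRatio(NA_real_), "NA")
  expect_equal(formatPrevalenceRatio(0), "NA")
})

test_that("HWE chi-square flags the homozygote-rich common variant", {
  # the common benign polymorphism: far more homozygotes than HWE expects
  chk <- hweConsistencyCheck(ac = 2377, an = 282912, nhom = 105,
                             sampleSize = 141456)
  expect_equal(chk$expected_hom, 141456 * (2377 / 282912)^2,
               tolerance = 1e-12)
  expect_equal(round(chk$expected_hom), 10)
  expect_equal(chk$observed_hom, 105)
  expect_gt(chk$chi_square, qchisq(0.999, df = 1))

  # a constructed variant with nhom = N q^2 sits at equilibrium
  N <- 10000; q <- 0.02
  nhom <- round(N * q^2)
  ac <- 2 * nhom + round(N * 2 * q * (1 - q))
  chk2 <- hweConsistencyCheck(ac = ac, an = 2 * N, nhom = nhom,
                              sampleSize = N)
  expect_lt(chk2$chi_square, 0.1)
})
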