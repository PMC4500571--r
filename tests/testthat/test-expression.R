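test_that("max normalization follows its definition and invariances", {
  t1 <- data.frame(LMPP = c(g1 = 3, g2 = 4), proB = c(g1 = 3, g2 = 1))
  n1 <- normalize_max(t1)
  expect_equal(unname(unlist(n1["g1", ])), c(1, 1))        # flat factor
  expect_equal(unname(unlist(n1["g2", ])), c(1, 0.25))     # (4, 1) -> (1, .25)
  # idempotent and scale-invariant
  expect_equal(normalize_max(n1), n1)
  expect_equal(normalize_max(t1 * 17.3), n1)
  # all-zero rows are left at zero with a warning
  t0 <- data.frame(LMPP = c(a = 0, b = 2), proB = c(a = 0, b = 1))
  expect_warning(n0 <- normalize_max(t0), "all-zero")
  expect_equal(unname(unlist(n0["a", ])), c(0, 0))
  expect_error(normalize_max(data.frame(LMPP = -1, proB = 1)),
               "non-negative")
})

test_that("model attractors normalize to 1 in their defining conditions", {
  att <- nominal_attractors()
  nm <- normalize_max(attractor_table(att))
  for (f in c("FLT3", "ZNF521")) expect_equal(nm[f, "LMPP"], 1)
  for (f in c("EBF1", "PAX5", "CD19")) expect_equal(nm[f, "proB"], 1)
})

test_that("concordance scores direction agreement and handles flats", {
  att <- nominal_attractors()
  mt <- attractor_table(att)
  # data equal to the model: full agreement
  cc <- concordance(mt, mt)
  expect_equal(cc$fraction, 1.0)
  # all directions inverted: zero agreement
  cc0 <- concordance(mt, mt[, c(2, 1)])
  expect_equal(cc0$fraction, 0.0)
  # flat factors are excluded from the denominator
  flat <- data.frame(LMPP = c(x = 2, y = 5), proB = c(x = 2.01, y = 1))
  cc_f <- concordance(flat, flat)
  expect_equal(cc_f$n_scored, 1)
  expect_error(concordance(mt[0, ], mt), "shared")
  # relabelling both condition columns consistently leaves the score alone
  cc_sw <- concordance(mt[, c(2, 1)], mt[, c(2, 1)])
  expect_equal(cc_sw$fraction, cc$fraction)
})

test_that("synthetic fixtures reproduce the commitment expression program", {
  fx <- make_expression_fixture(default_fixture_spec(noise_sd = 0.05),
                                seed = 1)
  att <- nominal_attractors()
  cc <- concordance(attractor_table(att), fx)
  keyed <- cc$per_factor[cc$per_factor$factor %in%
                           c("FLT3", "ZNF521", "EBF1", "PAX5", "CD19"), ]
  expect_true(all(keyed$scored))
  expect_true(all(keyed$match))
  expect_equal(cc$fraction, 1.0)
})

test_that("the differential-expression filter applies both cutoffs and
          recovers a planted truth exactly", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    fold_change_linear = c(1.5, -2.5, 3.0, -4.0),
                    p_value = c(0.01, 0.04, 0.2, 0.049))
  de <- de_filter(tab)
  expect_setequal(de$kept$gene, c("b", "d"))     # a: |fc| < 2; c: p >= .05
  expect_equal(de$n_down, 2)
  expect_equal(de$n_up, 0)
  expect_error(de_filter(data.frame(gene = "a")), "columns")

  planted <- make_de_table(n = 1000, n_planted = 100, seed = 3)
  de2 <- de_filter(planted)
  expect_identical(sort(de2$kept$gene), sort(planted$gene[planted$planted]))
  expect_equal(de2$n_up + de2$n_down, 100)
})

test_that("expression tables round-trip through TSV", {
  fx <- make_expression_fixture(seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(fx, path)
  back <- read_expression_tsv(path)
  expect_equal(as.matrix(back), as.matrix(fx), tolerance = 1e-12)
})
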