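test_that("PIH scoring sums items into the correct domains", {
  zero <- score_pih(rep(0, 12))
  expect_equal(unlist(zero[c("K", "P", "M", "C", "total")], use.names = FALSE),
               c(0, 0, 0, 0, 0))
  full <- score_pih(rep(8, 12))
  expect_equal(full$K, 16)
  expect_equal(full$P, 32)
  expect_equal(full$M, 16)
  expect_equal(full$C, 32)
  expect_equal(full$total, 96)

  # a hand-picked vector: items 1..12 = 1..8,1..4
  s <- score_pih(c(1:8, 1:4))
  expect_equal(s$K, 1 + 2)
  expect_equal(s$P, 3 + 4 + 5 + 6)
  expect_equal(s$M, 7 + 8)
  expect_equal(s$C, 1 + 2 + 3 + 4)
  expect_equal(s$KC, s$K + s$C)
  expect_equal(s$PM, s$P + s$M)
})

test_that("PIH scoring equals an independent per-item summation on random vectors", {
  m <- random_items(1000, seed = 20240501)
  got <- score_pih(m)
  # brute-force oracle: explicit per-row loops over item indices
  oracle <- t(apply(m, 1, function(r) {
    c(K = sum(r[1:2]), P = sum(r[3:6]), M = sum(r[7:8]), C = sum(r[9:12]))
  }))
  expect_equal(got$K, unname(oracle[, "K"]))
  expect_equal(got$P, unname(oracle[, "P"]))
  expect_equal(got$M, unname(oracle[, "M"]))
  expect_equal(got$C, unname(oracle[, "C"]))
  expect_equal(got$total, unname(rowSums(m)))
  expect_true(all(got$total >= 0 & got$total <= 96))
})

test_that("invalid PIH responses are rejected with the item named", {
  expect_error(score_pih(c(rep(4, 11), 9)), "pih_item_12")
  expect_error(score_pih(c(rep(4, 11), -1)), "pih_item_12")
  expect_error(score_pih(c(rep(4, 5), NA, rep(4, 6))), "pih_item_6")
  expect_error(score_pih(c(rep(4, 5), 4.5, rep(4, 6))), "pih_item_6")
  expect_error(score_pih(rep(4, 11)), "12 PIH items")
})

test_that("every banding scheme partitions its scale and is monotone in risk", {
  schemes <- banding_schemes()
  expect_setequal(names(schemes), c("16", "32", "48", "96"))
  for (key in names(schemes)) {
    sch <- schemes[[key]]
    cats <- band_score(0:sch$scale_max, sch)
    # partition: every integer score maps to exactly one category
    expect_false(anyNA(cats))
    expect_equal(sum(table(cats)), sch$scale_max + 1)
    # monotone: risk code never increases as the score increases
    codes <- category_code(cats)
    expect_true(all(diff(codes) <= 0))
    # extremes
    expect_equal(as.character(cats[1]), "poor")
    expect_equal(as.character(cats[sch$scale_max + 1]), "good")
  }
})

test_that("band edges reproduce the published lower bounds per category", {
  edges <- list(
    # scale, good lower, average lower, borderline lower
    `16` = c(12, 9, 6),
    `32` = c(20, 17, 12),
    `48` = c(30, 24, 18),
    `96` = c(56, 49, 41)
  )
  for (key in names(edges)) {
    e <- edges[[key]]
    expect_equal(as.character(band_score(e[1], as.numeric(key))), "good")
    expect_equal(as.character(band_score(e[1] - 1, as.numeric(key))), "average")
    expect_equal(as.character(band_score(e[2], as.numeric(key))), "average")
    expect_equal(as.character(band_score(e[2] - 1, as.numeric(key))), "borderline")
    expect_equal(as.character(band_score(e[3], as.numeric(key))), "borderline")
    expect_equal(as.character(band_score(e[3] - 1, as.numeric(key))), "poor")
  }
  # overlapping printed boundaries resolve to the better category's lower bound
  expect_equal(as.character(band_score(6, 16)), "borderline")
  expect_equal(as.character(band_score(20, 32)), "good")
})

test_that("96-point totals band as published", {
  expect_equal(as.character(band_score(58, 96)), "good")
  expect_equal(as.character(band_score(47, 96)), "borderline")
  expect_equal(as.character(band_score(0, 96)), "poor")
  expect_error(band_score(97, 96), "out of range")
  expect_error(band_score(-1, 16), "out of range")
})

test_that("categorize_lf bands every scale and designates the total as headline", {
  top <- categorize_lf(domain_scores(K = 16, P = 32, M = 16, C = 32))
  expect_true(all(vapply(top, function(x) all(x == "good"), logical(1))))

  one <- categorize_lf(domain_scores(K = 6, P = 17, M = 8, C = 16))
  expect_equal(as.character(one$K), "borderline")
  expect_equal(as.character(one$P), "average")
  expect_equal(as.character(one$M), "borderline")
  expect_equal(as.character(one$C), "borderline")
  expect_equal(as.character(one$total), "borderline") # total 47
  expect_equal(one$lf_category, one$total)

  # cohort banding is a partition: counts sum to cohort size
  m <- random_items(117, seed = 7)
  cats <- categorize_lf(score_pih(m))
  expect_equal(sum(table(cats$lf_category)), 117)
})

test_that("malformed banding schemes are rejected", {
  expect_error(
    banding_scheme(16,
                   lower = c(good = 12, average = 9, borderline = 7, poor = 0),
                   upper = c(good = 16, average = 11, borderline = 8, poor = 5)),
    "not a partition")
  expect_error(
    banding_scheme(16,
                   lower = c(good = 12, average = 9, borderline = 6, poor = 0),
                   upper = c(good = 16, average = 11, borderline = 8, poor = NA)),
    "bounds")
})
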