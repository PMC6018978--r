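test_that("column similarity is 1 for identical residues, normalized otherwise", {
  m <- blosum40()
  expect_identical(column_similarity(c("L", "L", "L", "L"), m), 1)
  # hand value from the matrix: B(L,I)=2, row maxima B(L,L)=B(I,I)=6,
  # s = (2/6 + 2/6)/2 = 1/3
  expect_equal(column_similarity(c("L", "I"), m), 1 / 3, tolerance = 1e-12)
  # fewer than two usable residues is a missing value, gaps/X excluded
  expect_true(is.na(column_similarity(c("L", "-"), m)))
  expect_true(is.na(column_similarity(c("L", "X"), m)))
  # permutation invariance and boundedness on random columns
  withr::with_seed(31, {
    for (i in 1:20) {
      col <- sample(c("L", "I", "V", "E", "Q", "G", "-"), 10, replace = TRUE)
      s1 <- column_similarity(col, m)
      s2 <- column_similarity(sample(col), m)
      if (is.na(s1)) expect_true(is.na(s2)) else {
        expect_identical(s1, s2)
        expect_lte(s1, 1)
      }
    }
  })
})

test_that("negative normalized scores are retained, not floored", {
  m <- blosum40()
  # B(L,G) = -4: the pair score must be negative
  expect_lt(column_similarity(c("L", "G"), m), 0)
})

test_that("one-sided normalization variants are available", {
  m <- blosum40()
  # B(C,S) = -1; max row C = 16, max row S = 5
  expect_equal(column_similarity(c("C", "S"), m, normalization = "first"),
               -1 / 16)
  expect_equal(column_similarity(c("C", "S"), m, normalization = "second"),
               -1 / 5)
  expect_equal(column_similarity(c("C", "S"), m),
               0.5 * (-1 / 16 - 1 / 5))
})

test_that("similarity_profile flags missing columns and maps positions", {
  fam <- aligned_family(c("a", "b", "c"),
                        c("LLE-", "LIE-", "LLEX"),
                        column_map = 101:104)
  prof <- similarity_profile(fam)
  expect_s3_class(prof, "similarity_profile")
  expect_identical(prof$position, 101:104)
  expect_identical(prof$similarity[1], 1)
  expect_true(is.na(prof$similarity[4]))
  expect_identical(prof$n_pairs, c(3L, 3L, 3L, 0L))
  # identical sequences score 1 everywhere
  same <- aligned_family(c("a", "b"), rep("MLKEQ", 2))
  expect_true(all(similarity_profile(same)$similarity == 1))
  expect_error(similarity_profile(aligned_family("a", "LLL")), "at least 2")
})

test_that("gap columns stay analysable through pairwise exclusion", {
  # two sequences gapped at a column: the remaining pair still scores
  fam <- aligned_family(c("a", "b", "c", "d"),
                        c("L-", "L-", "LL", "LL"))
  prof <- similarity_profile(fam)
  expect_identical(prof$similarity[2], 1)
  expect_identical(prof$n_pairs[2], 1L)
})

test_that("mann_whitney_u matches brute-force enumeration for small classes", {
  # independent oracle: enumerate all reassignments literally
  brute <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * length(y) / 2
    combs <- combn(length(pooled), n1)
    us <- apply(combs, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
  }
  withr::with_seed(17, {
    for (i in 1:20) {
      n1 <- sample(2:8, 1)
      n2 <- sample(2:8, 1)
      # mix of continuous and tied data
      x <- if (i %% 2) rnorm(n1) else sample(1:3, n1, replace = TRUE)
      y <- if (i %% 2) rnorm(n2) else sample(1:3, n2, replace = TRUE)
      got <- mann_whitney_u(x, y)
      want <- brute(x, y)
      expect_equal(got$U, want$U)
      expect_equal(got$p_value, want$p)
    }
  })
  # n1 = n2 = 3, tie-free: also matches the classical exact test
  x <- c(1.2, 3.4, 5.1)
  y <- c(2.2, 0.3, 7.7)
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("large-sample mann_whitney_u tracks the tie-corrected normal test", {
  withr::with_seed(23, {
    x <- round(rnorm(30), 1)
    y <- round(rnorm(40, 0.4), 1)
  })
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_match(got$method, "normal")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("identical class distributions are not declared significant", {
  withr::with_seed(5, {
    ps <- replicate(30, {
      pool <- rnorm(40)
      mann_whitney_u(pool[1:15], pool[16:40])$p_value
    })
  })
  expect_gt(median(ps), 0.05)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("interacting sites score as less variable on SEP3-style families", {
  fam <- simulate_family(preset_profiles("SEP3-like"), 78, label = "SEP3",
                         seed = 7)
  prof <- similarity_profile(fam)
  part <- default_site_partition()
  ct <- compare_site_classes(prof, part)
  expect_identical(ct$direction, "interacting_higher")
  expect_lt(ct$p_value, 0.01)
  expect_gt(ct$median_interacting, ct$median_non_interacting)
  expect_error(compare_site_classes(prof, site_partition(94:178)),
               "non-empty")
})

test_that("aa_frequency pools rare residues and sums to 1 per site", {
  fam <- aligned_family(
    sprintf("s%02d", 1:25),
    c(rep("LA", 24), "MA"))
  f <- aa_frequency(fam, sites = 1)
  expect_equal(sum(f$frequency), 1)
  expect_equal(f$frequency[f$residue == "L"], 0.96)
  expect_equal(f$frequency[f$residue == "others"], 0.04)
  # all-leucine column: single row, frequency 1
  f2 <- aa_frequency(fam, sites = 2)
  expect_identical(f2$residue, "A")
  expect_identical(f2$frequency, 1)
  # all-gap site is missing
  gapfam <- aligned_family(c("a", "b"), c("L-", "M-"))
  f3 <- aa_frequency(gapfam, sites = 2)
  expect_true(is.na(f3$frequency))
  expect_error(aa_frequency(fam, sites = 99), "outside")
  # simulated family recovers preset frequencies within 5 points
  sim <- simulate_family(preset_profiles("SEP3-like"), 78, label = "SEP3",
                         seed = 7)
  fs <- aa_frequency(sim, sites = 164)
  expect_gt(fs$frequency[fs$residue == "L"], 0.90)
})

test_that("hydropathy_profile averages the chosen scale per column", {
  kd <- hydropathy_scales()$kyte_doolittle
  fam <- aligned_family(c("a", "b"), c("LL", "LV"))
  h <- hydropathy_profile(fam)
  expect_equal(h$hydropathy[1], kd[["L"]])
  expect_equal(h$hydropathy[2], mean(c(kd[["L"]], kd[["V"]])))
  gapfam <- aligned_family(c("a", "b"), c("L-", "M-"))
  expect_true(is.na(hydropathy_profile(gapfam)$hydropathy[2]))
  expect_error(hydropathy_profile(fam, scale = "nope"), "unknown")
})

test_that("heptad registers honour the anchored phases", {
  expect_identical(heptad_register(164), "d")
  expect_identical(heptad_register(145), "d")
  expect_identical(heptad_register(c(161, 168)), c("a", "a"))
  # tetramerization-interface stripe: M150, L157, L164, L171 all at 'd'
  expect_identical(heptad_register(c(150, 157, 171)), rep("d", 3))
  expect_identical(heptad_register(154), "a")
  expect_error(heptad_register(50), "outside")
})

test_that("helical wheel advances 102.857 degrees per residue", {
  w <- helical_wheel(strrep("A", 15))
  step <- 360 * 2 / 7
  expect_equal(w$angle[2] - w$angle[1], step)
  # residues 7 apart coincide
  expect_equal(w$angle[8], w$angle[1])
  expect_equal(w$angle[15], w$angle[1])
  expect_identical(w$register[c(1, 8, 15)], rep("a", 3))
  # a and d of one heptad are ~51.4 degrees apart on the wheel
  sep <- abs(w$angle[4] - w$angle[1]) %% 360
  expect_equal(min(sep, 360 - sep), 51.42857, tolerance = 1e-4)
  expect_identical(w$angle[1], 0)
  expect_error(helical_wheel(""), "empty")
})

test_that("heptad periodicity score separates zippers from polar sequence", {
  # ideal leucine zipper: L at every a and d, polar elsewhere
  zipper <- paste(rep("LEELDEE", 6), collapse = "")
  s <- heptad_periodicity_score(zipper, window = 14)
  expect_true(all(s == 1))
  expect_true(all(heptad_periodicity_score(strrep("S", 30), 21) == 0))
  expect_error(heptad_periodicity_score("LLL", 14), "shorter")
  expect_error(heptad_periodicity_score(zipper, 10), "14, 21 or 28")
})

test_that("periodicity score equals brute-force all-phase enumeration", {
  withr::with_seed(99, {
    seqv <- sample(c("L", "I", "V", "E", "Q", "S", "K", "A"), 40,
                   replace = TRUE)
  })
  s <- heptad_periodicity_score(paste(seqv, collapse = ""), window = 14)
  hydro <- seqv %in% c("L", "I", "V", "M", "F", "A", "W", "Y")
  n_win <- 40 - 14 + 1
  win <- sapply(seq_len(n_win), function(st) {
    max(sapply(0:6, function(ph) {
      reg <- (seq(st, st + 13) - st + ph) %% 7
      mean(hydro[seq(st, st + 13)][reg %in% c(0, 3)])
    }))
  })
  expected <- sapply(1:40, function(i) {
    max(win[max(1, i - 13):min(i, n_win)])
  })
  expect_equal(s, expected)
})

test_that("substitution matrix reader reproduces known entries", {
  m <- blosum40()
  expect_identical(m["L", "L"], 6)
  expect_identical(m["L", "I"], 2)
  expect_identical(m["W", "W"], 19)
  expect_identical(m["C", "P"], -5)
  expect_true(all(rownames(m) == colnames(m)))
  # row maxima sit on the diagonal for the 20 canonical residues
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sub <- m[aas, aas]
  expect_true(all(diag(sub) == apply(sub, 1, max)))
})

test_that("aligned_family validates alphabet and shape", {
  expect_error(aligned_family(c("a", "b"), c("LL", "LLL")), "equal length")
  expect_error(aligned_family("a", "LZ"), "invalid residue")
  expect_error(aligned_family(c("a", "b"), c("LL", "LL"),
                              column_map = 1:3), "width")
})
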