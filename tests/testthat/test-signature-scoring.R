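test_that("GMT round-trips and rejects duplicates", {
  sigs <- list(gene_signature("a", c("g1", "g2")),
               gene_signature("b", c("g3", "g4", "g5")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sigs, path)
  back <- read_gmt(path)
  expect_equal(back$a$genes, c("g1", "g2"))
  expect_equal(back$b$genes, c("g3", "g4", "g5"))
  writeLines(c("a\tna\tg1", "a\tna\tg2"), path)
  expect_error(read_gmt(path), "duplicate")
})

test_that("module score is near zero for null signatures and detects plants", {
  set.seed(101)
  n_units <- 200
  expr <- matrix(rnorm(300 * n_units), nrow = 300,
                 dimnames = list(sprintf("g%03d", 1:300),
                                 sprintf("u%03d", 1:n_units)))
  # null: signature genes drawn at random look like their bin-mates
  scores <- vapply(1:50, function(s) {
    set.seed(s)
    sig <- sample(rownames(expr), 15)
    mean(module_score(expr, sig, seed = s))
  }, 0)
  expect_lt(abs(mean(scores)), 2 * sd(scores) / sqrt(length(scores)) + 0.02)

  # planted 4-fold elevation in half the units separates the score
  sig <- sprintf("g%03d", 1:15)
  hot <- 1:100
  expr2 <- expr
  expr2[sig, hot] <- expr2[sig, hot] + log(4)
  ms <- module_score(expr2, sig, seed = 1)
  expect_lt(wilcox.test(ms[hot], ms[-hot])$p.value, 0.01)
  expect_gt(median(ms[hot]), median(ms[-hot]))
})

test_that("module score is invariant to adding a constant", {
  expr <- make_expr(n_genes = 80, n_units = 25, seed = 3)
  sig <- rownames(expr)[c(5, 17, 33)]
  s1 <- module_score(expr, sig, seed = 11)
  s2 <- module_score(expr + 3.7, sig, seed = 11)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("module score errors when no signature gene is present", {
  expr <- make_expr()
  expect_error(module_score(expr, c("NOPE1", "NOPE2"), seed = 1), "NOPE1")
})

test_that("single-sample enrichment equals the term-by-term oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(6:10, 1)
    v <- setNames(rnorm(n), sprintf("g%d", 1:n))
    sig <- sample(names(v), sample(2:(n - 2), 1))
    expect_equal(ssgsea_score(v, sig), ssgsea_oracle(v, sig),
                 tolerance = 1e-12)
  }
})

test_that("single-sample enrichment is rank-invariant and maximal on top genes", {
  set.seed(8)
  v <- setNames(runif(40, 1, 5), sprintf("g%02d", 1:40))
  sig <- sample(names(v), 8)
  s0 <- ssgsea_score(v, sig)
  expect_equal(ssgsea_score(exp(v), sig), s0, tolerance = 1e-12)   # monotone
  expect_equal(ssgsea_score(rank(v), sig), s0, tolerance = 1e-12)  # transform
  # on an 8-gene toy, the top-3 set beats every other 3-subset
  v8 <- setNames(c(9, 7, 6, 4, 3, 2.5, 1, 0.5), letters[1:8])
  top <- names(sort(v8, decreasing = TRUE))[1:3]
  s_top <- ssgsea_score(v8, top)
  combos <- combn(names(v8), 3)
  all_scores <- apply(combos, 2, function(s) ssgsea_score(v8, s))
  expect_equal(max(all_scores), s_top, tolerance = 1e-12)
})

test_that("random signatures score near zero on average", {
  set.seed(99)
  v <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  draws <- vapply(1:1000, function(i)
    ssgsea_score(v, sample(names(v), 10)), 0)
  expect_lt(abs(mean(draws)), 2 * sd(draws) / sqrt(length(draws)) + 0.01)
})

test_that("score_matrix honours registry order, engines, and edge cases", {
  expr <- make_expr(n_genes = 120, n_units = 40, seed = 5)
  reg <- list(gene_signature("s1", rownames(expr)[1:10]),
              gene_signature("s2", rownames(expr)[20:30]))
  sc <- score_matrix(expr, reg, engine = "module", seed = 2)
  expect_equal(colnames(sc), c("s1", "s2"))
  single <- module_score(expr, reg[[1]], seed = derive_seed(2, "sig:s1"))
  expect_equal(sc[, "s1"], single)
  dup <- list(gene_signature("s1", "g001"), gene_signature("s1", "g002"))
  expect_error(score_matrix(expr, dup), "duplicate")
  empty <- expr[, 0, drop = FALSE]
  expect_equal(nrow(score_matrix(empty, reg, engine = "module")), 0)
})

test_that("both engines rank a planted elevation the same way", {
  set.seed(31)
  expr <- matrix(abs(rnorm(200 * 60)), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("u%02d", 1:60)))
  sig <- sprintf("g%03d", 1:12)
  hot <- 1:30
  expr[sig, hot] <- expr[sig, hot] * 4
  reg <- list(gene_signature("plant", sig))
  m <- score_matrix(expr, reg, engine = "module", seed = 4)[, 1]
  s <- score_matrix(expr, reg, engine = "ssgsea")[, 1]
  expect_gt(cor(m, s, method = "spearman"), 0.5)
  expect_gt(median(s[hot]), median(s[-hot]))
})

test_that("increasing the planted fold never lowers the median score", {
  base <- make_expr(n_genes = 150, n_units = 80, seed = 13)
  sig <- rownames(base)[1:10]
  hot <- 1:40
  meds_m <- meds_s <- numeric(0)
  for (fold in c(1, 2, 4, 8)) {
    e <- base
    e[sig, hot] <- e[sig, hot] * fold
    meds_m <- c(meds_m, median(module_score(e, sig, seed = 6)[hot]))
    meds_s <- c(meds_s, median(apply(e[, hot], 2, function(v) {
      names(v) <- rownames(e); ssgsea_score(v, sig)
    })))
  }
  expect_true(all(diff(meds_m) > -1e-9))
  expect_true(all(diff(meds_s) > -1e-9))
})
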