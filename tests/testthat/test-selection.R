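test_that("the univariate screen reproduces squared correlations", {
  yrs <- 1980:2010
  resp <- data.frame(year = yrs, value = rnorm(31))
  preds <- data.frame(year = yrs, self = resp$value)
  set.seed(31)
  for (k in 1:4) preds[[paste0("p", k)]] <- rnorm(31)
  scr <- univariate_r2_screen(resp, preds)
  expect_equal(scr$r.squared[scr$predictor == "self"], 1)
  for (k in 1:4) {
    expect_equal(scr$r.squared[scr$predictor == paste0("p", k)],
                 cor(resp$value, preds[[paste0("p", k)]])^2,
                 tolerance = 1e-12)
  }
  # insufficient overlap is reported, not fit
  preds$sparse <- NA_real_; preds$sparse[1:2] <- rnorm(2)
  scr2 <- univariate_r2_screen(resp, preds)
  expect_true(is.na(scr2$r.squared[scr2$predictor == "sparse"]))
})

make_sel_inputs <- function() {
  r2 <- data.frame(
    predictor = c("t_6_30", "t_total", "t_1_5", "t_lt1", "bear",
                  "win_a", "win_b"),
    r.squared = c(0.222, 0.193, 0.064, 0.025, 0.203, 0.10, 0.08),
    n = 40)
  hyp <- list(timber = c("t_6_30", "t_total", "t_1_5", "t_lt1"),
              predation = "bear",
              winter = c("win_a", "win_b"))
  corr <- diag(7)
  dimnames(corr) <- list(r2$predictor, r2$predictor)
  # the two best timber candidates are collinear with predator abundance
  corr["t_6_30", "bear"] <- corr["bear", "t_6_30"] <- 0.955
  corr["t_total", "bear"] <- corr["bear", "t_total"] <- 0.927
  corr["t_6_30", "t_total"] <- corr["t_total", "t_6_30"] <- 0.9
  list(r2 = r2, hyp = hyp, corr = corr)
}

test_that("collinear top candidates are replaced to keep all hypotheses", {
  inp <- make_sel_inputs()
  sel <- select_representatives(inp$r2, inp$hyp, inp$corr)
  expect_equal(unname(sel$chosen["timber"]), "t_1_5")
  expect_equal(unname(sel$chosen["predation"]), "bear")
  expect_equal(unname(sel$chosen["winter"]), "win_a")
  expect_length(sel$dropped, 0)
  expect_match(sel$substitutions, "timber")
})

test_that("without conflicts every hypothesis keeps its best candidate", {
  inp <- make_sel_inputs()
  corr0 <- diag(7); dimnames(corr0) <- dimnames(inp$corr)
  sel <- select_representatives(inp$r2, inp$hyp, corr0)
  expect_equal(unname(sel$chosen[c("timber", "predation", "winter")]),
               c("t_6_30", "bear", "win_a"))
  expect_length(sel$substitutions, 0)
})

test_that("selection maximizes retained hypotheses before total R^2", {
  # predation's lone candidate conflicts with every timber candidate:
  # dropping predation would allow the much stronger t_6_30, but keeping
  # both hypotheses must win
  inp <- make_sel_inputs()
  corr <- inp$corr
  for (p in inp$hyp$timber[-3])
    corr[p, "bear"] <- corr["bear", p] <- 0.99
  sel <- select_representatives(inp$r2, inp$hyp, corr)
  expect_setequal(names(sel$chosen), c("timber", "predation", "winter"))
  expect_equal(unname(sel$chosen["timber"]), "t_1_5")

  # when a hypothesis has no usable candidate at all, it is dropped
  for (p in inp$hyp$timber) corr[p, "bear"] <- corr["bear", p] <- 0.99
  sel2 <- select_representatives(inp$r2, inp$hyp, corr)
  # two hypotheses + the strongest timber candidate beat three weak ones?
  # no: retaining three is impossible, and among two-hypothesis sets the
  # exhaustive search keeps the pair with the greatest total R^2
  expect_equal(length(sel2$chosen), 2L)
  expect_gt(sum(inp$r2$r.squared[match(sel2$chosen, inp$r2$predictor)]),
            0.3)
})

test_that("selection is invariant to predictor ordering", {
  inp <- make_sel_inputs()
  perm <- c(5, 3, 1, 7, 2, 6, 4)
  r2p <- inp$r2[perm, ]
  corrp <- inp$corr[perm, perm]
  hyp_p <- lapply(inp$hyp, rev)
  sel1 <- select_representatives(inp$r2, inp$hyp, inp$corr)
  sel2 <- select_representatives(r2p, hyp_p, corrp)
  expect_equal(sel1$chosen[sort(names(sel1$chosen))],
               sel2$chosen[sort(names(sel2$chosen))])
})

test_that("the exhaustive search agrees with a brute-force oracle", {
  set.seed(33)
  for (rep in 1:5) {
    cand <- paste0("c", 1:6)
    hyp <- list(h1 = cand[1:2], h2 = cand[3:4], h3 = cand[5:6])
    r2 <- data.frame(predictor = cand, r.squared = runif(6), n = 30)
    M <- matrix(runif(36, -1, 1), 6); M <- (M + t(M)) / 2; diag(M) <- 1
    dimnames(M) <- list(cand, cand)
    sel <- select_representatives(r2, hyp, M, threshold = 0.5)
    # oracle: enumerate every subset of hypotheses and candidate choice
    best_n <- -1; best_r2 <- -1
    combos <- expand.grid(c(hyp$h1, NA), c(hyp$h2, NA), c(hyp$h3, NA),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      s <- na.omit(unlist(combos[i, ]))
      okc <- TRUE
      if (length(s) > 1) {
        mm <- abs(M[s, s]); diag(mm) <- 0
        okc <- max(mm) <= 0.5
      }
      if (!okc) next
      tot <- sum(r2$r.squared[match(s, r2$predictor)])
      if (length(s) > best_n ||
          (length(s) == best_n && tot > best_r2)) {
        best_n <- length(s); best_r2 <- tot
      }
    }
    expect_equal(length(sel$chosen), best_n)
    expect_equal(sum(r2$r.squared[match(sel$chosen, r2$predictor)]),
                 best_r2, tolerance = 1e-12)
    # returned set is conflict-free by construction
    if (length(sel$chosen) > 1) {
      mm <- abs(M[sel$chosen, sel$chosen]); diag(mm) <- 0
      expect_lte(max(mm), 0.5)
    }
  }
})
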