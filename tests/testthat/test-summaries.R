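freq_fixture <- function() {
  # deterministic classified-dive table: 2 seals x 2 sediments x day/night
  rows <- list()
  add <- function(seal, sed, diel, n_pel, n_ben, n_shal = 0) {
    types <- c(rep("pelagic", n_pel), rep("benthic", n_ben),
               rep("shallow", n_shal))
    rows[[length(rows) + 1]] <<- data.frame(
      seal_id = seal, sediment = sed, diel = diel, dive_type = types)
  }
  add("s1", "fine", "night", 5, 5)
  add("s1", "fine", "day", 2, 8)
  add("s1", "rock", "day", 1, 9)
  add("s2", "fine", "night", 6, 4)
  add("s2", "rock", "night", 3, 6, n_shal = 1)
  add("s2", "unclassified", "day", 5, 5)  # must be excluded
  do.call(rbind, rows)
}

test_that("pelagic frequency cells count correctly under both denominators", {
  d <- freq_fixture()
  cells <- pelagic_frequency_table(d, denominator = "all")
  s1fn <- cells[cells$seal_id == "s1" & cells$sediment == "fine" &
                  cells$diel == "night", ]
  expect_equal(s1fn$n_dives, 10)
  expect_equal(s1fn$freq, 0.5)
  # unclassified sediment never appears
  expect_false(any(cells$sediment == "unclassified"))
  # absent combinations are omitted, not zero-filled
  expect_false(any(cells$seal_id == "s1" & cells$sediment == "rock" &
                     cells$diel == "night"))
  # deep denominator drops the shallow dive from s2/rock/night
  deep <- pelagic_frequency_table(d, denominator = "deep")
  s2rn <- deep[deep$seal_id == "s2" & deep$sediment == "rock" &
                 deep$diel == "night", ]
  expect_equal(s2rn$n_dives, 9)
  expect_equal(s2rn$freq, 3 / 9)
  all_s2rn <- cells[cells$seal_id == "s2" & cells$sediment == "rock" &
                      cells$diel == "night", ]
  expect_equal(all_s2rn$n_dives, 10)
})

test_that("weighted cell means equal pooled count ratios", {
  d <- freq_fixture()
  cells <- pelagic_frequency_table(d, denominator = "all")
  fine_night <- cells[cells$sediment == "fine" & cells$diel == "night", ]
  pooled <- sum(fine_night$n_pelagic) / sum(fine_night$n_dives)
  weighted <- sum(fine_night$freq * fine_night$n_dives) /
    sum(fine_night$n_dives)
  expect_equal(weighted, pooled)
})

test_that("a constant response reports zero R-squared and F", {
  cells <- expand.grid(seal_id = c("s1", "s2", "s3"),
                       sediment = c("fine", "coarse", "rock"),
                       diel = c("day", "night"),
                       stringsAsFactors = FALSE)
  cells$n_dives <- 10; cells$n_pelagic <- 3; cells$freq <- 0.3
  # lm warns about the perfect fit; the report contract is what matters here
  m <- suppressWarnings(fit_frequency_model(cells))
  expect_equal(m$r_squared, 0)
  expect_true(all(m$anova[["F value"]] == 0, na.rm = TRUE))
})

test_that("a pure diel contrast loads on the diel term only", {
  cells <- expand.grid(seal_id = sprintf("s%d", 1:4),
                       sediment = c("fine", "coarse", "rock"),
                       diel = c("day", "night"),
                       stringsAsFactors = FALSE)
  cells$freq <- ifelse(cells$diel == "day", 0.2, 0.4)
  cells$n_dives <- 10; cells$n_pelagic <- round(cells$freq * 10)
  m <- suppressWarnings(fit_frequency_model(cells))  # exact fit, lm warns
  av <- m$anova
  # the fit is exact, so assert on the SS decomposition (F ratios are 0/0)
  expect_equal(av["sediment", "Sum Sq"], 0, tolerance = 1e-16)
  expect_gt(av["diel", "Sum Sq"] / sum(av[["Sum Sq"]]), 1 - 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-8)
  cm <- m$cell_means
  expect_equal(cm$mean_freq[cm$diel == "day"], rep(0.2, 3))
  expect_equal(cm$se, rep(0, 6), tolerance = 1e-12)
})

test_that("sequential F statistics match a projection-based oracle", {
  set.seed(77)
  cells <- expand.grid(seal_id = c("s1", "s2"),
                       sediment = c("fine", "coarse", "rock"),
                       diel = c("day", "night"),
                       stringsAsFactors = FALSE)
  cells$freq <- round(runif(nrow(cells), 0.1, 0.6), 3)
  cells$n_dives <- 20; cells$n_pelagic <- round(cells$freq * 20)
  m <- fit_frequency_model(cells)

  # independent sequential sums of squares via incremental QR projections
  y <- cells$freq
  X0 <- matrix(1, length(y), 1)
  blocks <- list(
    sediment = model.matrix(~ factor(cells$sediment,
                                     c("fine", "coarse", "rock")))[, -1],
    diel = model.matrix(~ factor(cells$diel, c("day", "night")))[, -1,
                                                                 drop = FALSE],
    seal_id = model.matrix(~ factor(cells$seal_id))[, -1, drop = FALSE])
  rss <- function(X) {
    q <- qr(X)
    sum(qr.resid(q, y)^2)
  }
  X <- X0
  prev <- rss(X)
  rank_prev <- qr(X)$rank
  ss <- df <- numeric(0)
  for (b in names(blocks)) {
    X <- cbind(X, blocks[[b]])
    cur <- rss(X)
    rank_cur <- qr(X)$rank
    ss[b] <- prev - cur
    df[b] <- rank_cur - rank_prev
    prev <- cur
    rank_prev <- rank_cur
  }
  df_resid <- length(y) - rank_prev
  ms_resid <- prev / df_resid
  av <- m$anova
  for (b in names(blocks)) {
    expect_equal(av[b, "Df"], unname(df[b]))
    f_oracle <- (ss[b] / df[b]) / ms_resid
    expect_equal(av[b, "F value"], unname(f_oracle), tolerance = 1e-8)
  }
  expect_equal(av["Residuals", "Df"], df_resid)
})

test_that("single-level factors are dropped, not fit rank-deficiently", {
  cells <- expand.grid(seal_id = c("s1", "s2", "s3"),
                       sediment = "fine",
                       diel = c("day", "night"),
                       stringsAsFactors = FALSE)
  cells$freq <- runif(nrow(cells))
  cells$n_dives <- 10; cells$n_pelagic <- 3
  expect_message(m <- fit_frequency_model(cells), "sediment")
  expect_equal(m$dropped, "sediment")
  expect_false("sediment" %in% rownames(m$anova))
})
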