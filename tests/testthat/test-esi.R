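test_that("min-max standardization handles forward, reverse and constant", {
  expect_equal(standardize_column(c(2, 4, 10), "forward"), c(0, 0.25, 1))
  expect_equal(standardize_column(c(2, 4, 10), "reverse"), c(1, 0.75, 0))
  expect_equal(standardize_column(c(5, 5, 5), "forward"), rep(0.5, 3))
  expect_error(standardize_column(3, "forward"), "at least 2")
  expect_error(standardize_column(c(1, NA), "forward"), "finite")
  # with two rows every non-constant column collapses to {0, 1}
  for (i in 1:10) {
    v <- sort(stats::runif(2))
    if (v[1] == v[2]) next
    expect_setequal(standardize_column(v, "forward"), c(0, 1))
  }
})

test_that("information entropy matches hand-computed values", {
  expect_equal(information_entropy(c(0.5, 0.5)), 1)
  expect_equal(information_entropy(c(0, 1)), 0)
  # -(0.25 log 0.25 + 0.75 log 0.75) / log 2
  expect_equal(information_entropy(c(0.25, 0.75)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(information_entropy(c(0.25, 0.75)), 4), 0.8113)
  expect_equal(information_entropy(c(0, 0, 0)), 1)
})

test_that("entropy weights match the direct formula transcription", {
  w <- entropy_weights(cbind(c(0, 1), c(0.5, 0.5)))$weights
  expect_equal(w, c(1, 0), tolerance = 1e-12)
  w2 <- entropy_weights(cbind(c(0, 1), c(0.25, 0.75)))$weights
  expect_equal(w2, oracle_entropy_weights(cbind(c(0, 1), c(0.25, 0.75))),
               tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(stats::runif(20), 5, 4)
    ew <- entropy_weights(m)
    expect_equal(ew$weights, oracle_entropy_weights(m), tolerance = 1e-12)
    expect_equal(sum(ew$weights), 1, tolerance = 1e-12)
    expect_true(all(ew$weights >= 0))
    expect_true(all(ew$entropy >= 0 & ew$entropy <= 1))
  }
})

test_that("block index is the weighted row sum", {
  expect_equal(block_index(rbind(c(0.3, 0.9)), c(1, 0)), 0.3)
  expect_equal(block_index(rbind(c(0.2, 0.8)), c(0.5, 0.5)), 0.5)
  expect_equal(block_index(matrix(1, 3, 2), c(0.4, 0.6)), rep(1, 3))
  expect_error(block_index(matrix(1, 2, 3), c(0.5, 0.5)), "match")
})

test_that("composite index is the geometric mean of status and calm", {
  expect_equal(composite_esi(0.5, 0.5), 0.5)
  expect_equal(composite_esi(1, 0), 1)
  expect_equal(composite_esi(0.36, 0.75), 0.3)
  expect_error(composite_esi(1.2, 0.5), "\\[0, 1\\]")
  expect_error(composite_esi(0.5, -0.1), "\\[0, 1\\]")
})

test_that("two-unit panel reproduces the hand-solved index", {
  # A dominates on status and has least pressure -> ESI 1; B the reverse -> 0
  pan <- as_indicator_panel(
    data.frame(id = c("A", "B"), name = c("A", "B"),
               lon = c(100, 110), lat = c(30, 40), year = 2013,
               s1 = c(10, 2), p1 = c(1, 5)), tiny_spec())
  r <- compute_esi(pan, tiny_spec())
  expect_equal(r$index$ESI, c(1, 0))
  expect_equal(r$index$Z, c(1, 0))
  expect_equal(r$index$Y, c(0, 1))
})

test_that("ESI is bounded, monotone and deterministic on random panels", {
  spec <- default_indicator_spec()
  for (s in 1:50) {
    panel <- gen_indicator_panel(n_units = 6, years = 2013,
                                 spec = spec, seed = s)
    r <- compute_esi(panel)
    expect_true(all(r$index$ESI >= 0 & r$index$ESI <= 1))
    expect_true(all(r$index$Z >= 0 & r$index$Z <= 1))
    expect_true(all(r$index$Y >= 0 & r$index$Y <= 1))
    # weights sum to 1 within each block
    for (blk in list("status", c("pressure", "response"))) {
      w <- r$weights$weight[r$weights$block %in% blk]
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= 0))
    }

    # raising a pressure(-) indicator of the second-lowest unit towards
    # (but not past) the column max leaves min/max — hence weights —
    # unchanged and must not raise that unit's ESI
    df <- as.data.frame(panel)
    col <- "population_density"
    i <- order(df[[col]])[2]
    target <- min(df[[col]]) + 0.9 * diff(range(df[[col]]))
    df2 <- df
    df2[[col]][i] <- max(df2[[col]][i], target)
    r2 <- compute_esi(as_indicator_panel(df2, spec))
    expect_lte(r2$index$ESI[i], r$index$ESI[i] + 1e-12)

    # raising a positive status indicator likewise must not lower ESI
    col_s <- "forest_cover_rate"
    j <- order(df[[col_s]])[2]
    target_s <- min(df[[col_s]]) + 0.9 * diff(range(df[[col_s]]))
    df3 <- df
    df3[[col_s]][j] <- max(df3[[col_s]][j], target_s)
    r3 <- compute_esi(as_indicator_panel(df3, spec))
    expect_gte(r3$index$ESI[j], r$index$ESI[j] - 1e-12)
  }
  # determinism
  p1 <- gen_indicator_panel(n_units = 10, seed = 7)
  p2 <- gen_indicator_panel(n_units = 10, seed = 7)
  expect_identical(compute_esi(p1)$index, compute_esi(p2)$index)
})

test_that("a constant column gets zero weight and no influence", {
  spec <- indicator_spec(c("s1", "s2", "p1"),
                         c("status", "status", "pressure"),
                         c("positive", "positive", "negative"))
  df <- data.frame(id = letters[1:4], name = letters[1:4],
                   lon = 100:103, lat = 30:33, year = 2013,
                   s1 = c(1, 2, 3, 4), s2 = 7, p1 = c(4, 3, 2, 1))
  r <- compute_esi(as_indicator_panel(df, spec), spec)
  expect_equal(r$weights$weight[r$weights$indicator == "s2"], 0)
  df2 <- df
  df2$s2 <- 99
  r2 <- compute_esi(as_indicator_panel(df2, spec), spec)
  expect_equal(r$index$ESI, r2$index$ESI)
})
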