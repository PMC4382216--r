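test_that("grid classification uses half-open cell ownership", {
  m <- half_half_map()
  expect_equal(classify_point(m, 250, 250), "natural")
  expect_equal(classify_point(m, 750, 250), "pasture")
  # a corner point belongs to the cell opening to its north-east
  expect_equal(classify_point(m, 500, 100), "pasture")
  expect_equal(classify_point(m, 499.999, 100), "natural")
  expect_error(classify_point(m, 1001, 100), "out of extent")
})

test_that("polygon classification resolves ties to the first-listed feature", {
  p1 <- simple_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10))
  p2 <- simple_polygon(c(10, 20, 20, 10), c(0, 0, 10, 10))
  m <- landcover_polygons(list(p1, p2), c("natural", "degraded"))
  expect_equal(classify_point(m, 5, 5), "natural")
  expect_equal(classify_point(m, 15, 5), "degraded")
  expect_equal(classify_point(m, 50, 50), "pasture")  # background
})

test_that("classification frequencies match a 50/50 map", {
  m <- half_half_map()
  set.seed(4)
  px <- runif(1000, 0, 1000); py <- runif(1000, 0, 500)
  f <- mean(classify_point(m, px, py) == "natural")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("availability circles reach the farthest MCP vertex", {
  sq <- simple_polygon(c(-100, 100, 100, -100), c(-100, -100, 100, 100))
  c1 <- availability_circle(data.frame(x = 0, y = 0), sq)
  expect_equal(c1$radius, 100 * sqrt(2))
  c2 <- availability_circle(data.frame(x = c(0, 10), y = c(0, 0)), sq)
  expect_equal(unname(c2$center), c(5, 0))
  set.seed(6)
  for (i in 1:10) {
    h <- convex_hull_polygon(rnorm(15, 0, 200), rnorm(15, 0, 200))
    r <- data.frame(x = runif(1, -50, 50), y = runif(1, -50, 50))
    circ <- availability_circle(r, h)
    expect_true(all(sqrt((h$x - circ$center[1])^2 +
                         (h$y - circ$center[2])^2) <= circ$radius + 1e-9))
  }
  expect_error(availability_circle(data.frame(x = numeric(0), y = numeric(0)),
                                   sq), "invalid")
})

test_that("composition fractions are conserved and match geometry", {
  m <- half_half_map()
  # circle centred on the class boundary: symmetric split
  comp <- composition(m, list(center = c(500, 250), radius = 150), cell = 1)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_equal(unname(comp["natural"]), 0.5, tolerance = 1e-3)
  expect_equal(unname(comp["pasture"]), 0.5, tolerance = 1e-3)
  # region fully inside one patch
  one <- composition(m, list(center = c(200, 250), radius = 100))
  expect_equal(unname(one["natural"]), 1)
  # polygon region vs Monte-Carlo point sampling
  poly <- simple_polygon(c(300, 800, 700, 350), c(100, 150, 400, 380))
  comp_p <- composition(m, poly, cell = 2)
  set.seed(8)
  n_mc <- 1e5
  sx <- runif(n_mc, 300, 800); sy <- runif(n_mc, 100, 400)
  inside <- frugitrack:::point_in_ring(poly, sx, sy)
  mc <- mean(classify_point(m, sx[inside], sy[inside]) == "natural")
  expect_equal(unname(comp_p["natural"]), mc, tolerance = 0.01)
})

test_that("selection ratios recover no-selection and simple arithmetic", {
  cats <- c("a", "b")
  av <- matrix(0.5, 3, 2, dimnames = list(1:3, cats))
  null_used <- matrix(50, 3, 2, dimnames = list(1:3, cats))
  s0 <- selection_ratios(null_used, av)
  expect_equal(s0$wi, c(1, 1))
  expect_equal(attr(s0, "chi2"), 0)
  used <- matrix(rep(c(75, 25), each = 3), 3, 2, dimnames = list(1:3, cats))
  s <- selection_ratios(used, av)
  expect_equal(s$wi, c(1.5, 0.5))
  expect_true(all(s$ci_low >= 0))
  expect_error(selection_ratios(used[1, , drop = FALSE], av[1, , drop = FALSE]))
})

test_that("selection chi-square accumulates per-animal log-likelihood terms", {
  cats <- c("a", "b", "c")
  av <- matrix(1 / 3, 4, 3, dimnames = list(1:4, cats))
  set.seed(10)
  used <- t(sapply(1:4, function(i) rmultinom(1, 60, c(0.5, 0.3, 0.2))))
  colnames(used) <- cats
  s <- selection_ratios(used, av)
  E <- matrix(20, 4, 3)
  manual <- 2 * sum(used * log(used / E), na.rm = TRUE)
  expect_equal(attr(s, "chi2"), manual)
  expect_equal(attr(s, "df"), 4 * (3 - 1))
})

test_that("exact Fisher p-values agree with brute-force enumeration", {
  t22 <- matrix(c(3, 1, 1, 3), 2, 2)
  expect_equal(fisher_exact_rxc(t22), fisher_brute(t22), tolerance = 1e-7)
  # identical rows carry no evidence
  expect_equal(fisher_exact_rxc(matrix(c(5, 5, 2, 2), 2, 2)), 1)
  # empty column is dropped before testing
  t_with_zero <- matrix(c(4, 1, 0, 0, 2, 5), 2, 3)
  expect_equal(fisher_exact_rxc(t_with_zero),
               fisher_brute(t_with_zero[, c(1, 3)]), tolerance = 1e-7)
  expect_error(fisher_exact_rxc(matrix(c(1.5, 1, 2, 2), 2, 2)), "invalid")
  # oracle sweep over small 2x2 and 2x3 tables
  set.seed(11)
  for (i in 1:15) {
    K <- sample(2:3, 1)
    tab <- matrix(rpois(2 * K, 3), 2, K)
    if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2) next
    expect_equal(fisher_exact_rxc(tab),
                 fisher_brute(tab[, colSums(tab) > 0, drop = FALSE]),
                 tolerance = 1e-6)
  }
})

test_that("Holm step-down rejects a prefix of the sorted p-values", {
  all_small <- holm_bonferroni(rep(0.0005, 5))
  expect_true(all(all_small$reject))
  expect_equal(min(all_small$threshold), 0.05 / 5)
  expect_true(holm_bonferroni(0.04)$reject)
  mixed <- holm_bonferroni(c(0.011, 0.02, 0.9))
  expect_equal(mixed$reject, c(TRUE, TRUE, FALSE))
  expect_equal(mixed$threshold, c(0.05 / 3, 0.05 / 2, 0.05))
  # agreement with the standard adjusted-p formulation
  set.seed(12)
  p <- runif(8)^2
  expect_equal(holm_bonferroni(p)$reject,
               stats::p.adjust(p, method = "holm") <= 0.05)
})
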