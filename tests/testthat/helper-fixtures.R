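# deterministic fixtures shared across test files

# frozen 12-point LoCoH instance (runif, seed 42, rounded to mm)
locoh12 <- function() {
  data.frame(
    x = c(91.481, 93.708, 28.614, 83.045, 64.175, 51.91, 73.659, 13.467,
          65.699, 70.506, 45.774, 71.911),
    y = c(93.467, 25.543, 46.229, 94.001, 97.823, 11.749,
          47.5, 56.033, 90.403, 13.871, 98.889, 94.667)
  )
}

# two tight clusters 1 km apart, 20 points each (rnorm sd 30, seed 7)
two_cluster_40 <- function() {
  set.seed(7)
  data.frame(x = c(rnorm(20, 0, 30), rnorm(20, 1000, 30)),
             y = c(rnorm(20, 0, 30), rnorm(20, 0, 30)))
}

# half natural / half pasture grid map split at x = 500
half_half_map <- function() {
  codes <- matrix(3L, 50, 100)
  codes[, 1:50] <- 0L
  landcover_grid(codes, xll = 0, yll = 0, cellsize = 10)
}

# small synthetic study shared by pipeline tests (built once per run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_study(n_bats = 4, commuter_fraction = 0.25,
                               sessions = 3, seed = 11)
    cache
  }
})

# brute-force Fisher p: full enumeration of 2xK tables with fixed margins
fisher_brute <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); K <- ncol(tab)
  logp <- function(m) sum(lchoose(cs, m[1, ]))
  cells <- expand.grid(lapply(cs, function(cj) 0:cj))
  cells <- cells[rowSums(cells) == rs[1], , drop = FALSE]
  lp <- apply(cells, 1, function(r) logp(rbind(r, cs - r)))
  obs <- logp(tab)
  sum(exp(lp[lp <= obs + 1e-7])) / sum(exp(lp))
}

# edge-zone roost inside a natural patch (mirrors the study generator)
find_natural_roost <- function(land, patch = 1, seed = 1) {
  set.seed(seed)
  centers <- land$truth$patch_centers
  radii <- land$truth$patch_radii
  repeat {
    ang <- runif(1, 0, 2 * pi)
    roost <- centers[patch, ] + runif(1, 0.6, 0.85) * radii[patch] *
      c(cos(ang), sin(ang))
    if (classify_point(land$map, roost[1], roost[2]) == "natural")
      return(roost)
  }
}

# degraded cell 300-1100 m from the roost, near the 660 m mean commute
far_degraded_site <- function(map, roost) {
  cells <- which(map$codes == 1L, arr.ind = TRUE)
  xy <- cbind(map$xll + (cells[, 2] - 0.5) * map$cellsize,
              map$yll + (cells[, 1] - 0.5) * map$cellsize)
  d <- sqrt((xy[, 1] - roost[1])^2 + (xy[, 2] - roost[2])^2)
  ok <- which(d >= 300 & d <= 1100)
  xy[ok[which.min(abs(d[ok] - 660))], ]
}
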