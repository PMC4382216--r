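#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain with the defaults of the
#' study design it implements: 15-165 degree bearing separation, 400 m
#' range limit, 50 m stationary radius, 95% MCP, 50% LoCoH isopleths with
#' `k = round(sqrt(n))`, design-III selection at `alpha = 0.05`, and
#' delta-2 AICc conditional model averaging.
#'
#' @param projection free-text label of the projected CRS of the inputs
#'   (never used for computation; coordinates are planar meters).
#' @param sep_bounds,max_range,stationary_radius,declination filter stage.
#' @param mcp_level,locoh_fraction,k_rounding home-range stage.
#' @param alpha,used_mode selection stage (`used_mode` `"fixes"` counts
#'   fixes inside the focus areas, `"area"` uses isopleth area fractions).
#' @param scope,mode,ci_multiplier model stage (see [model_average()]).
#' @param min_contact_fraction,n_sessions daily-range session selection.
#' @param seed global seed for any stochastic fallback.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(projection = "local transverse Mercator (m)",
                            sep_bounds = c(15, 165), max_range = 400,
                            stationary_radius = 50, declination = 0,
                            mcp_level = 95, locoh_fraction = 0.5,
                            k_rounding = "round",
                            alpha = 0.05, used_mode = c("fixes", "area"),
                            scope = "delta2", mode = "conditional",
                            ci_multiplier = 1.96,
                            min_contact_fraction = 0.85, n_sessions = 3,
                            seed = 1) {
  used_mode <- match.arg(used_mode)
  stopifnot(sep_bounds[1] >= 0, sep_bounds[2] <= 180,
            sep_bounds[1] < sep_bounds[2],
            max_range > 0, stationary_radius >= 0,
            mcp_level > 0, mcp_level <= 100,
            locoh_fraction > 0, locoh_fraction <= 1,
            alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full telemetry-to-inference pipeline
#'
#' Chains all stages: triangulation and filtering of the bearing table,
#' stationary deduplication, session assignment, per-bat home ranges (MCP,
#' LoCoH, compactness, focus areas), daily ranges with habitat
#' composition, design-III selection ratios against per-bat availability
#' circles, and the all-subset daily-range model set with averaged
#' coefficients. Results are returned as a list of tables and optionally
#' written to `out_dir` together with a run manifest.
#'
#' @param bearings bearing table (see [read_bearings_csv()]).
#' @param map a land-cover map.
#' @param roosts data frame `bat_id`, `x`, `y` (several rows per bat
#'   allowed).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for the report CSVs.
#' @param sessions optional session windows per bat (list of data frames
#'   with `start`, `end`); by default sessions are inferred from >2 h gaps.
#' @return list with `fixes`, `rejections`, `home_ranges` (per-bat table),
#'   `daily` (daily-range records with covariate placeholders filled from
#'   composition), `selection` (selection-ratio table with chi2/df/p
#'   attributes), `model_table`, `averaged`, `focus_composition`,
#'   `home_range_objects`, `config`.
#' @export
run_pipeline <- function(bearings, map, roosts, config = pipeline_config(),
                         out_dir = NULL, sessions = NULL) {
  tri <- triangulate_bearings(bearings, max_range = config$max_range,
                              sep_bounds = config$sep_bounds,
                              declination = config$declination)
  # noisy biangulation can place a fix beyond the mapped extent; such
  # fixes cannot be classified and are dropped like any other rejection
  if (inherits(map, "landcover_grid")) {
    ok <- tri$fixes$x >= map$xll &
      tri$fixes$x < map$xll + ncol(map$codes) * map$cellsize &
      tri$fixes$y >= map$yll &
      tri$fixes$y < map$yll + nrow(map$codes) * map$cellsize
    if (any(!ok)) {
      warning(sum(!ok), " fix(es) outside the land-cover extent dropped")
      tri$rejections <- rbind(tri$rejections,
                              data.frame(timestamp = tri$fixes$timestamp[!ok],
                                         bat_id = tri$fixes$bat_id[!ok],
                                         reason = "off-map"))
      tri$fixes <- tri$fixes[ok, , drop = FALSE]
    }
  }
  bats <- unique(tri$fixes$bat_id)
  hr_rows <- list(); hr_objs <- list(); daily_rows <- list()
  used_counts <- list(); avail_rows <- list(); focus_rows <- list()
  all_fixes <- list()

  for (b in bats) {
    f <- tri$fixes[tri$fixes$bat_id == b, , drop = FALSE]
    f <- assign_sessions(f, sessions = sessions[[b]])
    f <- do.call(rbind, lapply(split(f, f$session_id),
                               deduplicate_stationary,
                               stationary_radius = config$stationary_radius))
    if (nrow(f) < 9) {
      warning("bat ", b, " excluded: too few fixes after filtering")
      next
    }
    all_fixes[[b]] <- f
    hr <- home_range(f, mcp_level = config$mcp_level,
                     locoh_fraction = config$locoh_fraction,
                     k_rounding = config$k_rounding)
    hr_objs[[b]] <- hr
    hr_rows[[b]] <- data.frame(bat_id = b, hr_tot_ha = hr$hr_tot_ha,
                               n_fixes = hr$n_fixes,
                               compactness = hr$compactness,
                               n_focus_areas = hr$n_focus_areas)
    # daily ranges with habitat composition of each daily MCP
    dr <- daily_ranges(f, level = config$mcp_level)
    if (!is.null(dr)) {
      dr$disturbance <- vapply(dr$polygon, function(p)
        composition(map, p)["degraded"], numeric(1))
      dr$bat_id <- b
      daily_rows[[b]] <- dr[, c("bat_id", "session_id", "n_fixes", "area",
                                "log_area", "disturbance")]
    }
    # used habitat: fixes inside the 50% isopleth components
    iso <- hr$isopleth
    cats <- classify_point(map, f$x[iso$covered], f$y[iso$covered])
    used_counts[[b]] <- table(factor(cats, levels = landcover_categories()))
    rs <- roosts[roosts$bat_id == b, , drop = FALSE]
    if (nrow(rs) > 0) {
      circ <- availability_circle(rs, hr$mcp95)
      avail_rows[[b]] <- composition(map, circ)
    }
    # per-component composition of the focus areas (near vs far)
    if (nrow(rs) > 0 && length(iso$components) > 0) {
      ctr <- c(mean(rs$x), mean(rs$y))
      members <- focus_membership(iso, f$x[iso$covered], f$y[iso$covered])
      for (ci in seq_along(iso$components)) {
        member <- iso$covered[members[[ci]]]
        ccats <- classify_point(map, f$x[member], f$y[member])
        cx <- mean(f$x[member]); cy <- mean(f$y[member])
        tab <- table(factor(ccats, levels = landcover_categories()))
        focus_rows[[paste(b, ci)]] <- data.frame(
          bat_id = b, component = ci,
          dist_to_roost = sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2),
          n_fixes = length(member),
          t(as.matrix(tab)))
      }
    }
  }

  home_ranges <- do.call(rbind, hr_rows)
  rownames(home_ranges) <- NULL
  daily <- do.call(rbind, daily_rows)
  if (!is.null(daily)) rownames(daily) <- NULL
  focus_composition <- do.call(rbind, focus_rows)
  if (!is.null(focus_composition)) rownames(focus_composition) <- NULL

  # design-III selection over bats with both use and availability
  sel <- NULL
  ok <- intersect(names(used_counts), names(avail_rows))
  ok <- ok[vapply(used_counts[ok], sum, numeric(1)) > 0]
  if (length(ok) >= 2) {
    used <- do.call(rbind, lapply(used_counts[ok], as.numeric))
    colnames(used) <- landcover_categories()
    avail <- do.call(rbind, lapply(avail_rows[ok], as.numeric))
    colnames(avail) <- landcover_categories()
    rownames(used) <- rownames(avail) <- ok
    sel <- selection_ratios(used, avail, alpha = config$alpha)
  }

  # daily-range model set (needs the full covariate set; day comes from the
  # session order, moon/sex are external covariates - absent here they are
  # filled as non-informative placeholders and flagged)
  model_table <- averaged <- NULL
  if (!is.null(daily) && length(unique(daily$bat_id)) >= 2 &&
      nrow(daily) >= 12) {
    daily$day <- daily$session_id
    if (is.null(daily$moon)) daily$moon <- 0.5
    if (is.null(daily$sex)) daily$sex <- 0
    terms <- c("disturbance", "day", "moon", "sex")
    usable <- terms[vapply(daily[terms], function(v) stats::sd(v) > 0,
                           logical(1))]
    cen <- center_covariates(daily, terms = usable)
    set <- all_subsets(cen$data, terms = usable)
    model_table <- set$table
    averaged <- model_average(set, scope = config$scope, mode = config$mode,
                              ci_multiplier = config$ci_multiplier)
  }

  out <- list(fixes = do.call(rbind, all_fixes),
              rejections = tri$rejections,
              home_ranges = home_ranges, daily = daily,
              selection = sel, model_table = model_table,
              averaged = averaged, focus_composition = focus_composition,
              home_range_objects = hr_objs, config = config)
  if (!is.null(out$fixes)) rownames(out$fixes) <- NULL
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

# writes the report bundle: one CSV per table + manifest
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) if (!is.null(d))
    utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wr(result$fixes, "fixes.csv")
  wr(result$rejections, "rejections.csv")
  wr(result$home_ranges, "home_ranges.csv")
  if (!is.null(result$daily))
    wr(result$daily[, setdiff(names(result$daily), "polygon")], "daily_ranges.csv")
  if (!is.null(result$selection)) {
    sel <- result$selection
    wr(sel, "selection.csv")
  }
  wr(result$model_table, "model_set.csv")
  wr(result$averaged, "averaged_coefficients.csv")
  wr(result$focus_composition, "focus_composition.csv")
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("frugitrack")),
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    selection_chi2 = if (!is.null(result$selection))
      attr(result$selection, "chi2"),
    selection_df = if (!is.null(result$selection))
      attr(result$selection, "df"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

# order-stable hash of the configuration (no external digest dependency)
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # FNV-1a over the UTF-8 bytes, printed as hex
  h <- 2166136261
  for (byte in utf8ToInt(s)) {
    h <- bitwXor(h, byte %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Summary statistics of a published-style home-range table
#'
#' Desk-level geometry re-analysis: mean, SD, min and max of the
#' total-home-range column and the Pearson correlation between the
#' log-transformed home-range sizes and the compactness ratios.
#'
#' @param table data frame with columns `hr_tot_ha` and `compactness`
#'   (e.g. [dermanura_homeranges()]).
#' @return list with `mean`, `sd`, `min`, `max` (ha) and `correlation`
#'   (see [pearson_log_correlation()]).
#' @export
geometry_summary <- function(table) {
  stopifnot(all(c("hr_tot_ha", "compactness") %in% names(table)))
  list(mean = mean(table$hr_tot_ha), sd = stats::sd(table$hr_tot_ha),
       min = min(table$hr_tot_ha), max = max(table$hr_tot_ha),
       correlation = pearson_log_correlation(table$hr_tot_ha,
                                             table$compactness))
}
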