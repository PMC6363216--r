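#' Configuration of a full posture analysis
#'
#' Either point at input files (`tps` + `welfare_csv`) or supply a
#' [population_spec()] to run on synthetic data. Every requested combination
#' of scheme x condition x region is analysed.
#'
#' @param tps path to a TPS landmark file (or `NULL` for synthetic input).
#' @param welfare_csv path to the per-horse welfare table.
#' @param population a [population_spec()] used when `tps` is `NULL`.
#' @param schemes character vector of scheme names (`"ssl"`, `"mixed"`).
#' @param regions regions to analyse (`"full"`, `"back_croup"`,
#'   `"neck_head"`).
#' @param conditions photographing conditions to analyse.
#' @param stabilize_neck_angle stabilize the 1-15-30 articulation angle
#'   before superimposition of full-outline analyses.
#' @param n_components components reported (components beyond this are never
#'   reported, matching the convention of dropping axes under 10% variance
#'   after the third).
#' @param seed integer seed for all stochastic stages.
#' @param out_dir output directory for tables, grids and the run log.
#' @param write_grids write deformation-grid SVGs.
#' @param gpa_tol,slide_tol,slide_max convergence controls passed to [gpa()]
#'   and [slide_semilandmarks()].
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(tps = NULL, welfare_csv = NULL, population = NULL,
                            schemes = c("ssl", "mixed"),
                            regions = "full",
                            conditions = "standing",
                            stabilize_neck_angle = TRUE,
                            n_components = 3,
                            seed = 1L,
                            out_dir = NULL,
                            write_grids = !is.null(out_dir),
                            gpa_tol = 1e-8, slide_tol = 1e-6, slide_max = 5) {
  if (is.null(tps) && is.null(population)) {
    stop("either a TPS file or a population spec is required", call. = FALSE)
  }
  stopifnot(length(schemes) >= 1, length(regions) >= 1, length(conditions) >= 1)
  structure(list(tps = tps, welfare_csv = welfare_csv, population = population,
                 schemes = schemes, regions = regions, conditions = conditions,
                 stabilize_neck_angle = stabilize_neck_angle,
                 n_components = n_components, seed = as.integer(seed),
                 out_dir = out_dir, write_grids = write_grids,
                 gpa_tol = gpa_tol, slide_tol = slide_tol,
                 slide_max = slide_max),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Accepts the same fields as [analysis_config()]; the `population` entry is
#' a mapping of [population_spec()] arguments.
#'
#' @param path YAML file.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$population)) {
    pop <- y$population
    if (!is.null(pop$photos_per_individual)) {
      pop$photos_per_individual <- unlist(pop$photos_per_individual)
    }
    if (!is.null(pop$between_sd)) pop$between_sd <- unlist(pop$between_sd)
    if (!is.null(pop$base)) pop$base <- do.call(profile_params, pop$base)
    y$population <- do.call(population_spec, pop)
  }
  do.call(analysis_config, y)
}

#' Run the full posture-welfare analysis
#'
#' For each scheme x condition x region combination: optional articulation
#' angle stabilization (full outline only), Generalized Procrustes Analysis,
#' semilandmark sliding against the consensus, shape PCA, then a mixed-model
#' ANOVA of each reported component against every welfare indicator and
#' categorical covariate (Pearson correlation of per-horse mean scores for
#' quantitative covariates). Writes per-combination ANOVA/variance tables as
#' CSV, deformation grids as SVG, and a JSON run log; all outputs are
#' deterministic given the config and seed.
#'
#' @param config an [analysis_config()].
#' @return Invisibly, a list of per-combination bundles (`gpa`, `sliding`,
#'   `pca`, `anova_table`, `grids`), plus `records` and `log`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  t_start <- Sys.time()

  if (!is.null(config$tps)) {
    full <- read_tps(config$tps)
    records <- read_welfare_csv(config$welfare_csv)
  } else {
    pop <- config$population
    pop$seed <- config$seed
    gen <- generate_population(pop)
    full <- gen$sample
    records <- gen$records
  }
  missing_ids <- setdiff(unique(full$info$horse_id), records$horse_id)
  if (length(missing_ids)) {
    stop("no welfare record for horse(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "tables"), recursive = TRUE, showWarnings = FALSE)
    if (config$write_grids) {
      dir.create(file.path(out_dir, "grids"), recursive = TRUE, showWarnings = FALSE)
    }
  }

  indicator_cols <- intersect(c("sb_arb", "depressed", "ear_category",
                                "type_of_equid", "proportion", "paddock_social"),
                              names(records))
  numeric_cols <- intersect(c("hay_meals", "paddock_time",
                              "visible_conspecifics", "work_hours"),
                            names(records))

  combos <- expand.grid(scheme = config$schemes, condition = config$conditions,
                        region = config$regions, stringsAsFactors = FALSE)
  bundles <- list()
  log_stages <- list()

  for (ci in seq_len(nrow(combos))) {
    sch_name <- combos$scheme[ci]
    cond <- combos$condition[ci]
    region <- combos$region[ci]
    tag <- sprintf("%s_%s_%s", sch_name, cond, region)
    t0 <- Sys.time()

    keep <- full$info$condition == cond
    if (!any(keep)) next
    sub <- shape_sample(full$coords[, , keep, drop = FALSE],
                        full$info[keep, , drop = FALSE],
                        method_scheme(sch_name))
    if (region == "full" && config$stabilize_neck_angle) {
      sub <- stabilize_articulation_angle(sub)
    }
    if (region != "full") sub <- select_region(sub, region)

    slid <- slide_semilandmarks(sub, outer_max = config$slide_max,
                                tol = config$slide_tol)
    pca <- shape_pca(slid$gpa)
    k <- min(config$n_components, ncol(pca$scores))

    tab <- anova_table(pca, records, k, indicator_cols, numeric_cols)
    grids <- list()
    for (comp in seq_len(k)) {
      for (ext in c("min", "max")) {
        gr <- deformation_grid(pca, comp, ext)
        grids[[sprintf("PC%d_%s", comp, ext)]] <- gr
        if (!is.null(out_dir) && config$write_grids) {
          svg_path <- file.path(out_dir, "grids",
                                sprintf("%s_PC%d_%s.svg", tag, comp, ext))
          grDevices::svg(svg_path, width = 8, height = 5)
          plot(gr)
          grDevices::dev.off()
        }
      }
    }
    if (!is.null(out_dir)) {
      utils::write.csv(tab, file.path(out_dir, "tables",
                                      sprintf("anova_%s.csv", tag)),
                       row.names = FALSE)
      vf <- data.frame(component = paste0("PC", seq_len(k)),
                       variance_pct = round(100 * pca$variance_fraction[seq_len(k)], 4))
      utils::write.csv(vf, file.path(out_dir, "tables",
                                     sprintf("variance_%s.csv", tag)),
                       row.names = FALSE)
    }
    bundles[[tag]] <- list(gpa = slid$gpa, sliding = slid, pca = pca,
                           anova_table = tab, grids = grids)
    log_stages[[tag]] <- list(
      n_photos = sum(keep),
      n_individuals = length(unique(sub$info$horse_id)),
      variance_pct = round(100 * pca$variance_fraction[seq_len(k)], 3),
      gpa_iterations = slid$gpa$iterations,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }
  if (!length(bundles)) stop("no scheme/condition/region combination produced data",
                             call. = FALSE)

  run_log <- list(
    package = "equimorph",
    version = as.character(utils::packageVersion("equimorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    tolerances = list(gpa_tol = config$gpa_tol, slide_tol = config$slide_tol,
                      slide_max = config$slide_max),
    combinations = log_stages,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(c(bundles, list(records = records, log = run_log)))
}

# indicator/covariate x PC grid of mixed-ANOVA (or Pearson) results
anova_table <- function(pca, records, k, indicator_cols, numeric_cols) {
  info <- pca$info
  idx <- match(info$horse_id, records$horse_id)
  rows <- list()
  for (col in indicator_cols) {
    vals <- records[[col]][idx]
    if (length(unique(stats::na.omit(vals))) < 2) next
    row <- list(variable = col, test = "mixed_anova")
    for (comp in seq_len(k)) {
      res <- tryCatch(
        suppressWarnings(mixed_anova_pc(pca$scores[, comp], vals,
                                        info$horse_id, label = col,
                                        component = comp)),
        error = function(e) NULL
      )
      row[[sprintf("PC%d_F", comp)]] <- if (is.null(res)) NA_real_ else round(res$F, 6)
      row[[sprintf("PC%d_p", comp)]] <- if (is.null(res)) NA_real_ else signif(res$p, 6)
    }
    rows[[col]] <- as.data.frame(row)
  }
  ind_means <- rowsum(pca$scores[, seq_len(k), drop = FALSE], info$horse_id) /
    as.vector(table(info$horse_id)[sort(unique(info$horse_id))])
  rec_idx <- match(rownames(ind_means), records$horse_id)
  for (col in numeric_cols) {
    vals <- records[[col]][rec_idx]
    if (stats::var(vals, na.rm = TRUE) == 0) next
    row <- list(variable = col, test = "pearson")
    for (comp in seq_len(k)) {
      res <- tryCatch(pearson_cor(ind_means[, comp], vals),
                      error = function(e) NULL)
      row[[sprintf("PC%d_F", comp)]] <- if (is.null(res)) NA_real_ else round(res$r, 6)
      row[[sprintf("PC%d_p", comp)]] <- if (is.null(res)) NA_real_ else signif(res$p, 6)
    }
    rows[[col]] <- as.data.frame(row)
  }
  do.call(rbind, rows)
}
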