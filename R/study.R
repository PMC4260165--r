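#' Configuration for a simulation study
#'
#' The full published grid is `n_test` in `seq(1, 29, by = 2)`, five inner
#' designs (LOO and leave-20/40/60/80%-out with 50 repeats), 80 outer
#' partitions and 200 simulations per combination -- hours to days on one
#' CPU.  `scale` multiplies `n_sim`, `n_outer` and the LMO repeat counts
#' (rounded up, minimum 1) for desk-scale runs.
#'
#' @param population a `dcv_population`.
#' @param selectors named list of `dcv_selector` objects.
#' @param designs named list of `dcv_design` objects.
#' @param n_test_grid integer vector of outer test-set sizes.
#' @param n_outer outer partitions per run (default 80).
#' @param n_sim simulation repeats per combination (default 200).
#' @param n_oracle oracle test-set size (default 5000).
#' @param seed study seed: all other seeds derive from it.
#' @param scale scale multiplier in `(0, 1]`.
#' @param out_dir optional output directory for tidy CSV + JSON manifest.
#' @return an object of class `dcv_study_config`.
#' @export
study_config <- function(population, selectors, designs,
                         n_test_grid = seq(1L, 29L, by = 2L),
                         n_outer = 80L, n_sim = 200L, n_oracle = 5000L,
                         seed = 1L, scale = 1, out_dir = NULL) {
  stopifnot(inherits(population, "dcv_population"),
            length(selectors) >= 1, length(designs) >= 1,
            all(vapply(selectors, inherits, logical(1), "dcv_selector")),
            all(vapply(designs, inherits, logical(1), "dcv_design")),
            scale > 0, scale <= 1)
  if (is.null(names(selectors))) {
    names(selectors) <- vapply(selectors, selector_label, character(1))
  }
  if (is.null(names(designs))) {
    names(designs) <- vapply(designs, function(d) {
      if (d$scheme == "LMO") sprintf("CV-%d%%", round(100 * d$leave_out_fraction))
      else if (d$scheme == "KFOLD") sprintf("%d-fold", d$n_folds)
      else "LOO"
    }, character(1))
  }
  up <- function(x) max(1L, as.integer(ceiling(x * scale)))
  designs <- lapply(designs, function(d) {
    if (d$scheme == "LMO") d$n_repeats <- up(d$n_repeats)
    d
  })
  n <- population$n
  if (any(n_test_grid >= n)) stop("every n_test must be smaller than n")
  structure(list(population = population, selectors = selectors,
                 designs = designs, n_test_grid = as.integer(n_test_grid),
                 n_outer = up(n_outer), n_sim = up(n_sim),
                 n_oracle = as.integer(n_oracle), seed = as.integer(seed),
                 scale = scale, out_dir = out_dir),
            class = "dcv_study_config")
}

#' Run a simulation study over the configured grid
#'
#' Iterates simulations x selectors x designs x test sizes.  Within one
#' simulation repeat the SAME generated sample and oracle set are used for
#' every selector/design combination, and the outer partitions are shared
#' across selectors and designs at a given test size (seed discipline), so
#' that technique comparisons are paired.  Per combination the per-simulation
#' figures of merit are aggregated with [study_average()] and the relative
#' deviation of `ave.PE` from `ave.PE_theo` is reported.
#'
#' @param config a `dcv_study_config`.
#' @return a list of class `dcv_study` with `per_sim` (tidy data frame, one
#'   row per simulation x combination), `summary` (one row per combination),
#'   `frequencies` (variable selection frequencies per combination) and
#'   `manifest` (all parameters and seeds).  If `config$out_dir` is set, the
#'   three tables are also written as CSV plus a JSON manifest.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "dcv_study_config"))
  pop <- config$population
  rows <- list()
  freq_acc <- list()
  for (r in seq_len(config$n_sim)) {
    sim_seed <- derive_seed(config$seed, 10L, r)
    sample <- sample_dataset(pop, seed = sim_seed)
    oracle <- sample_oracle(pop, n_oracle = config$n_oracle, seed = sim_seed)
    for (si in seq_along(config$selectors)) {
      sel_name <- names(config$selectors)[si]
      sel <- config$selectors[[si]]
      for (di in seq_along(config$designs)) {
        des_name <- names(config$designs)[di]
        des <- config$designs[[di]]
        for (nt in config$n_test_grid) {
          # same dcv seed for all selectors/designs at (r, nt): shared partitions
          res <- run_double_cv(sample, sel, des, n_test = nt,
                               n_outer = config$n_outer,
                               seed = derive_seed(config$seed, 11L, r, nt),
                               oracle = oracle, population = pop)
          combo <- paste(sel_name, des_name, nt, sep = "|")
          sizes <- vapply(res$records,
                          function(x) length(x$selected$subset), numeric(1))
          ranks <- vapply(res$records,
                          function(x) as.numeric(x$selected$rank %||% NA_real_),
                          numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            sim = r, selector = sel_name, design = des_name, n_test = nt,
            pe = res$pe_dcv, pe_internal = res$pe_internal_dcv,
            pe_oracle = res$pe_oracle_dcv %||% NA_real_,
            pe_theo = res$pe_theo_dcv %||% NA_real_,
            vb_pe = res$vb_pe,
            vb_pe_oracle = res$vb_pe_oracle %||% NA_real_,
            mean_subset_size = mean(sizes),
            mean_rank = if (all(is.na(ranks))) NA_real_
                        else mean(ranks, na.rm = TRUE),
            stringsAsFactors = FALSE)
          f <- variable_frequencies(res)
          if (is.null(freq_acc[[combo]])) {
            freq_acc[[combo]] <- f
          } else {
            freq_acc[[combo]] <- freq_acc[[combo]] + f
          }
        }
      }
    }
  }
  per_sim <- do.call(rbind, rows)
  combos <- unique(per_sim[c("selector", "design", "n_test")])
  summary <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- merge(per_sim, combos[i, ])
    avg <- study_average(sub[c("pe", "pe_internal", "pe_oracle", "pe_theo",
                               "vb_pe", "vb_pe_oracle", "mean_subset_size",
                               "mean_rank")])
    get <- function(stat, col) avg[[col]][avg$statistic == stat]
    data.frame(combos[i, ], ave_pe = get("pe", "mean"),
               se_pe = get("pe", "se"),
               ave_pe_internal = get("pe_internal", "mean"),
               ave_pe_oracle = get("pe_oracle", "mean"),
               ave_pe_theo = get("pe_theo", "mean"),
               ave_vb_pe = get("vb_pe", "mean"),
               rel_dev = if (is.finite(get("pe_theo", "mean")))
                 rel_dev(get("pe", "mean"), get("pe_theo", "mean"))
                 else NA_real_,
               mean_subset_size = get("mean_subset_size", "mean"),
               mean_rank = get("mean_rank", "mean"),
               n_sim = nrow(sub), stringsAsFactors = FALSE)
  }))
  freq <- do.call(rbind, lapply(names(freq_acc), function(combo) {
    parts <- strsplit(combo, "|", fixed = TRUE)[[1]]
    data.frame(selector = parts[1], design = parts[2],
               n_test = as.integer(parts[3]),
               variable = seq_along(freq_acc[[combo]]),
               frequency = freq_acc[[combo]] / config$n_sim,
               stringsAsFactors = FALSE)
  }))
  manifest <- list(model_label = pop$model_label, p = pop$p, n = pop$n,
                   rho = pop$rho, sigma2 = pop$sigma2,
                   selectors = names(config$selectors),
                   designs = lapply(config$designs, unclass),
                   n_test_grid = config$n_test_grid,
                   n_outer = config$n_outer, n_sim = config$n_sim,
                   n_oracle = config$n_oracle, seed = config$seed,
                   scale = config$scale)
  out <- structure(list(per_sim = per_sim, summary = summary,
                        frequencies = freq, manifest = manifest),
                   class = "dcv_study")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_sim, file.path(config$out_dir, "per_sim.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(freq, file.path(config$out_dir, "frequencies.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.dcv_study <- function(x, ...) {
  cat(sprintf("<dcv_study: %d simulations, %d combinations>\n",
              x$manifest$n_sim, nrow(x$summary)))
  print(x$summary, digits = 4)
  invisible(x)
}
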