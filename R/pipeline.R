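#' Run the full thermoregulation analysis pipeline
#'
#' Orchestrates every stage on a field CSV or a synthetic configuration:
#' validation and size-class assignment; monthly body-temperature comparisons
#' across the four sex-by-size classes (Kruskal-Wallis with Dunn's post hoc);
#' per-group regressions of thermoregulation capacity Tb - S on surface
#' temperature with per-sex ANCOVA and PERMANOVA; thermoregulation-axes
#' regressions (burrow use efficiency E_B and no-refuge offset b) on the
#' records with burrow readings, again with per-sex ANCOVA/PERMANOVA; onset
#' temperature estimates T_reg per group; and small-vs-large contrasts within
#' each sex.
#'
#' @param input Path to a CSV of field records, or a [synthetic_config()].
#' @param seed Integer seed driving the permutation tests (and recorded in the
#'   report). A synthetic input's data are governed by the config's own seed.
#' @param n_perm Permutations for the PERMANOVA tests (default 999; the
#'   permutation p floor is 1/(n_perm + 1)).
#' @param transform Response transform for the female axes ANCOVA hypothesis
#'   test: "none" (default) or "offset_sqrt". Parameter estimates are always
#'   computed on the untransformed degrees-Celsius scale.
#' @param size_as Treat size as the dichotomous class ("class", default) or
#'   as continuous carapace width ("continuous") in ANCOVA/PERMANOVA.
#' @param month_filter Optional character vector of months to retain.
#' @param out_dir Optional directory; when given, [write_report()] is called.
#' @param plausibility_window Temperature validity window, degrees C.
#' @return Object of class `run_report`; see [write_report()] for the files
#'   it serializes to.
#' @export
run_pipeline <- function(input, seed = 1L, n_perm = 999,
                         transform = c("none", "offset_sqrt"),
                         size_as = c("class", "continuous"),
                         month_filter = NULL, out_dir = NULL,
                         plausibility_window = c(0, 60)) {
  transform <- match.arg(transform)
  size_as <- match.arg(size_as)

  if (inherits(input, "synthetic_config")) {
    ds <- generate_dataset(input)
    rs <- validate_records(ds$records,
                           plausibility_window = plausibility_window)
    provenance <- list(kind = "synthetic", config_seed = input$seed,
                       groups = names(input$groups))
    truth <- ds$truth
  } else if (is.character(input) && length(input) == 1) {
    rs <- read_records(input, plausibility_window = plausibility_window)
    provenance <- list(kind = "file", path = input)
    truth <- NULL
  } else {
    stop("input must be a CSV path or a synthetic_config")
  }

  rec <- rs$records
  if (!is.null(month_filter)) {
    keep <- rec$month %in% normalize_month(month_filter)
    rec <- rec[keep, , drop = FALSE]
  }
  if (nrow(rec) == 0) stop("validation left no usable records [stage: validate]")
  rec <- rec[rec$size_class != "out_of_range", , drop = FALSE]
  if (nrow(rec) == 0) stop("no records fall in the analyzable size classes [stage: classify]")

  rec$thermoreg_capacity_c <- rec$body_temp_c - rec$surface_temp_c
  groups_present <- intersect(setdiff(size_class_levels(), "out_of_range"),
                              unique(rec$size_class))

  ## monthly Tb comparisons -------------------------------------------------
  monthly <- list()
  for (mo in intersect(month_levels(), unique(rec$month))) {
    sub <- rec[rec$month == mo, , drop = FALSE]
    gl <- split(sub$body_temp_c, sub$size_class)
    gl <- gl[vapply(gl, length, 1L) > 0]
    if (length(gl) >= 2) {
      kw <- kruskal_wallis(gl)
      dn <- tryCatch(dunn_posthoc(gl), error = function(e) NULL)
      monthly[[mo]] <- list(
        medians = vapply(gl, stats::median, 1.0),
        kruskal = kw, dunn = dn
      )
    }
  }

  ## Tb - S vs S regressions and per-sex tests ------------------------------
  fit_or_null <- function(x, y) {
    tryCatch(fit_ols(x, y), error = function(e) NULL)
  }
  tbs_fits <- lapply(stats::setNames(groups_present, groups_present),
                     function(g) {
    sub <- rec[rec$size_class == g, , drop = FALSE]
    fit_or_null(sub$surface_temp_c, sub$thermoreg_capacity_c)
  })

  sex_tests <- function(covariate_col, data, seed_offset) {
    out <- list()
    for (sx in intersect(c("female", "male"), unique(data$sex))) {
      dat <- data[data$sex == sx, , drop = FALSE]
      size_var <- if (size_as == "class") {
        sub("_(fe)?male$", "", dat$size_class)
      } else {
        dat$carapace_width_mm
      }
      tr <- if (sx == "female") transform else "none"
      anc <- tryCatch(
        ancova(dat$thermoreg_capacity_c, size_var, dat[[covariate_col]],
               transform = tr),
        error = function(e) list(error = conditionMessage(e)))
      size_num <- if (is.numeric(size_var)) size_var
                  else as.numeric(factor(size_var))
      prm <- tryCatch(
        permanova(dat$thermoreg_capacity_c,
                  terms = list(covariate = dat[[covariate_col]],
                               size = size_var,
                               `size:covariate` =
                                 size_num * dat[[covariate_col]]),
                  n_perm = n_perm,
                  seed = seed + seed_offset + (sx == "male")),
        error = function(e) list(error = conditionMessage(e)))
      out[[sx]] <- list(ancova = anc, permanova = prm)
    }
    out
  }
  tbs_tests <- sex_tests("surface_temp_c", rec, seed_offset = 0L)

  ## thermoregulation axes ---------------------------------------------------
  has_b <- !is.na(rec$burrow_temp_c)
  axes_section <- NULL
  eb_fits <- stats::setNames(vector("list", length(groups_present)),
                             groups_present)
  if (any(has_b)) {
    axes <- compute_axes(rec[has_b, , drop = FALSE])
    eb_fits <- lapply(stats::setNames(groups_present, groups_present),
                      function(g) {
      sub <- axes[axes$size_class == g, , drop = FALSE]
      tryCatch(estimate_eb(sub), error = function(e) NULL)
    })
    axes_tests <- sex_tests("cooling_capacity_c", axes, seed_offset = 2L)
    axes_section <- list(n = nrow(axes), tests = axes_tests)
  } else {
    axes_section <- list(n = 0L, reason = "not computable: no burrow readings")
  }

  ## onset estimates and contrasts ------------------------------------------
  estimates <- lapply(stats::setNames(groups_present, groups_present),
                      function(g) {
    tbs <- tbs_fits[[g]]; ebf <- eb_fits[[g]]
    treg <- if (!is.null(tbs) && !is.null(ebf)) estimate_treg(tbs, ebf)
            else NULL
    list(group = g, tbs_fit = tbs, eb_fit = ebf, treg = treg,
         tb_sensitivity = if (!is.null(tbs)) implied_tb_sensitivity(tbs)
                          else NA_real_)
  })
  contrasts <- list()
  for (sx in c("female", "male")) {
    a <- estimates[[paste0("small_", sx)]]
    b <- estimates[[paste0("large_", sx)]]
    if (!is.null(a$eb_fit) && !is.null(b$eb_fit)) {
      contrasts[[sx]] <- group_contrast(a, b)
    }
  }

  report <- structure(list(
    provenance = provenance,
    options = list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                   transform = transform, size_as = size_as,
                   month_filter = month_filter,
                   version = as.character(utils::packageVersion("crabtherm"))),
    counts = rs$counts,
    validation = rs$validation,
    n_analyzed = nrow(rec),
    n_with_burrow = sum(has_b),
    monthly = monthly,
    tbs_tests = tbs_tests,
    axes = axes_section,
    estimates = estimates,
    contrasts = contrasts,
    records = rec,
    truth = truth
  ), class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Per-group estimates table of a pipeline run
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return data.frame with one row per sex-by-size group: sample sizes, E_B
#'   and b with standard errors, the surface-regression slope m and intercept
#'   c, the onset surface temperature, T_reg with its upper bound and
#'   delta-method SE, and the implied body-warming rate per degree of surface
#'   warming. Temperatures rounded to 2 decimals at this reporting step only.
#' @export
estimates_table <- function(report) {
  stopifnot(inherits(report, "run_report"))
  rows <- lapply(report$estimates, function(e) {
    tbs <- e$tbs_fit; ebf <- e$eb_fit; tr <- e$treg
    data.frame(
      group = e$group,
      n = if (!is.null(tbs)) tbs$n else 0L,
      n_axes = if (!is.null(ebf)) ebf$n else 0L,
      e_b = if (!is.null(ebf)) round(ebf$e_b, 2) else NA_real_,
      e_b_se = if (!is.null(ebf)) round(ebf$slope_se, 3) else NA_real_,
      b_offset = if (!is.null(ebf)) round(ebf$b_offset, 2) else NA_real_,
      b_offset_se = if (!is.null(ebf)) round(ebf$intercept_se, 3) else NA_real_,
      m = if (!is.null(tbs)) round(tbs$slope, 2) else NA_real_,
      c = if (!is.null(tbs)) round(tbs$intercept, 2) else NA_real_,
      r_squared_s = if (!is.null(tbs)) round(tbs$r_squared, 2) else NA_real_,
      r_squared_axes = if (!is.null(ebf)) round(ebf$r_squared, 2) else NA_real_,
      tb_sensitivity = round(e$tb_sensitivity, 2),
      surface_at_onset = if (!is.null(tr) && is.null(tr$reason))
        round(tr$surface_at_onset, 2) else NA_real_,
      t_reg = if (!is.null(tr) && is.null(tr$reason))
        round(tr$t_reg, 2) else NA_real_,
      t_reg_upper = if (!is.null(tr) && is.null(tr$reason))
        round(tr$t_reg_upper, 2) else NA_real_,
      t_reg_se = if (!is.null(tr) && is.null(tr$reason))
        round(tr$t_reg_se, 2) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("Thermoregulation pipeline report\n")
  cat(sprintf("  input: %s; %d records analyzed (%d with burrow readings)\n",
              x$provenance$kind, x$n_analyzed, x$n_with_burrow))
  cat(sprintf("  rows read %d: accepted %d (flagged %d), rejected %d\n",
              x$counts["total"], x$counts["accepted"], x$counts["flagged"],
              x$counts["rejected"]))
  cat("\nPer-group estimates:\n")
  print(estimates_table(x), row.names = FALSE)
  invisible(x)
}

ancova_to_list <- function(a) {
  if (is.null(a)) return(NULL)
  if (!inherits(a, "ancova_result")) return(a)
  list(table = a$table, n = a$n, transform_applied = a$transform_applied,
       size_type = a$size_type)
}

permanova_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  if (!inherits(p, "permanova_result")) return(p)
  list(table = p$table, n_perm = p$n_perm, seed = p$seed)
}

#' Write a pipeline report to disk
#'
#' Writes `estimates.tsv` (the [estimates_table()]), `tests.json` (monthly
#' Kruskal/Dunn, ANCOVA and PERMANOVA tables with their seeds),
#' `report.json` (everything, including provenance, options, and validation
#' counts; the write timestamp is an isolated top-level field so re-runs with
#' identical inputs and seeds are otherwise byte-identical), and diagnostic
#' scatter plots under `figures/`.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if needed).
#' @param figures Write diagnostic PNGs (default TRUE).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, figures = TRUE) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  est <- estimates_table(report)
  utils::write.table(est, file.path(out_dir, "estimates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  tests <- list(
    monthly = lapply(report$monthly, function(m) list(
      medians = as.list(m$medians),
      kruskal = list(h = m$kruskal$h_statistic, df = m$kruskal$df,
                     p = m$kruskal$p_value,
                     group_ns = as.list(m$kruskal$group_ns)),
      dunn = if (!is.null(m$dunn)) m$dunn$comparisons else NULL
    )),
    tbs_vs_s = lapply(report$tbs_tests, function(sx) list(
      ancova = ancova_to_list(sx$ancova),
      permanova = permanova_to_list(sx$permanova))),
    axes = if (!is.null(report$axes$tests)) {
      lapply(report$axes$tests, function(sx) list(
        ancova = ancova_to_list(sx$ancova),
        permanova = permanova_to_list(sx$permanova)))
    } else report$axes$reason
  )
  jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  full <- list(
    generated_at = format(Sys.time(), tz = "UTC"),
    provenance = report$provenance,
    options = report$options,
    counts = as.list(report$counts),
    n_analyzed = report$n_analyzed,
    n_with_burrow = report$n_with_burrow,
    estimates = est,
    contrasts = lapply(report$contrasts, function(cc) cc$contrasts),
    validation = report$validation,
    tests = tests
  )
  jsonlite::write_json(full, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  if (figures) {
    figdir <- file.path(out_dir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    rec <- report$records
    grDevices::png(file.path(figdir, "capacity_vs_surface.png"),
                   width = 900, height = 700, res = 110)
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    for (g in names(report$estimates)) {
      sub <- rec[rec$size_class == g, , drop = FALSE]
      graphics::plot(sub$surface_temp_c, sub$thermoreg_capacity_c,
                     xlab = "surface temperature (degC)",
                     ylab = "Tb - S (degC)", main = g, pch = 19,
                     col = grDevices::adjustcolor("steelblue", 0.6))
      f <- report$estimates[[g]]$tbs_fit
      if (!is.null(f)) graphics::abline(f$intercept, f$slope, col = "firebrick")
    }
    grDevices::dev.off()
    if (!is.null(report$axes$tests)) {
      grDevices::png(file.path(figdir, "thermoregulation_axes.png"),
                     width = 900, height = 700, res = 110)
      graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
      axes <- compute_axes(rec[!is.na(rec$burrow_temp_c), , drop = FALSE])
      for (g in names(report$estimates)) {
        sub <- axes[axes$size_class == g, , drop = FALSE]
        graphics::plot(sub$cooling_capacity_c, sub$thermoreg_capacity_c,
                       xlab = "B - S (degC)", ylab = "Tb - S (degC)",
                       main = g, pch = 19,
                       col = grDevices::adjustcolor("darkorange", 0.6))
        f <- report$estimates[[g]]$eb_fit
        if (!is.null(f)) graphics::abline(f$intercept, f$slope,
                                          col = "firebrick")
      }
      grDevices::dev.off()
    }
  }
  invisible(out_dir)
}
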