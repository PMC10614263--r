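#' Assemble a group table
#'
#' The unit of analysis is the cell; the animal id is carried so that
#' per-animal averaging is available when cells within an animal should not
#' be treated as independent. Rows with non-finite values (e.g. undefined
#' stability indices from zero-event cells) are dropped with a message
#' reporting the count.
#'
#' @param group,animal_id,cell_id,value Vectors of equal length.
#' @param measurement Name of the measurement (e.g. `"stability_index"`).
#' @param units Units string (e.g. `"um"`, `"ratio"`).
#' @return A data frame of class `group_table` with attributes `measurement`
#'   and `units`.
#' @export
group_table <- function(group, animal_id, cell_id, value,
                        measurement = "value", units = "") {
  df <- data.frame(group = as.character(group),
                   animal_id = as.character(animal_id),
                   cell_id = cell_id, value = as.numeric(value))
  bad <- !is.finite(df$value)
  if (any(bad)) {
    message(sprintf("%s: dropping %d row(s) with undefined values",
                    measurement, sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  structure(df, class = c("group_table", "data.frame"),
            measurement = measurement, units = units)
}

#' Per-group n, mean and SEM
#'
#' The descriptive summary convention for this kind of data: mean +/- SEM,
#' with SEM = sd / sqrt(n). Groups with fewer than two observations get an
#' `NA` SEM and a warning.
#'
#' @param table A [group_table()] (or data frame with `group` and `value`).
#' @return A data frame with columns `group`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(table) {
  stopifnot(is.data.frame(table), all(c("group", "value") %in% names(table)))
  groups <- unique(table$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- table$value[table$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_)
  }))
  if (any(out$n < 2L))
    warning("group(s) with n < 2: SEM not defined")
  rownames(out) <- NULL
  out
}

#' Compare groups: unpaired t-test or one-way ANOVA with Tukey HSD
#'
#' Two groups are compared with a two-sided unpaired t-test (pooled variance
#' by default, Welch optionally); three or more with a one-way ANOVA followed
#' by all-pairs Tukey honest-significant-difference comparisons.
#'
#' @param table A [group_table()].
#' @param var_equal Pooled-variance t-test (default `TRUE`); `FALSE` for
#'   Welch.
#' @param per_animal Average cells within each animal first, then compare
#'   animal means (default `FALSE`: per-cell analysis).
#' @return A list of class `group_comparison`: `summary` (per-group n, mean,
#'   SEM), `method`, `statistic`, `p_value`, and for >= 3 groups a `tukey`
#'   data frame of pairwise adjusted p-values.
#' @export
compare_groups <- function(table, var_equal = TRUE, per_animal = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("group", "value") %in% names(table)))
  df <- as.data.frame(table)
  if (per_animal) {
    if (!"animal_id" %in% names(df))
      stop("`per_animal = TRUE` requires an `animal_id` column", call. = FALSE)
    agg <- stats::aggregate(value ~ group + animal_id, data = df, FUN = mean)
    df <- data.frame(group = agg$group, value = agg$value)
  }
  groups <- unique(df$group)
  if (length(groups) < 2L)
    stop("need at least 2 groups to compare", call. = FALSE)
  ns <- table(df$group)
  if (any(ns < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  summ <- summarize_groups(df)
  df$group <- factor(df$group)
  if (length(groups) == 2L) {
    tt <- t.test(value ~ group, data = df, var.equal = var_equal)
    res <- list(summary = summ, method = if (var_equal) "t" else "welch_t",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, tukey = NULL)
  } else {
    fit <- aov(value ~ group, data = df)
    av <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    res <- list(summary = summ, method = "anova_tukey",
                statistic = av[["F value"]][1],
                df = av[["Df"]],
                p_value = av[["Pr(>F)"]][1],
                tukey = data.frame(comparison = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   row.names = NULL))
  }
  res$measurement <- attr(table, "measurement")
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %s: statistic = %.4g, p = %.4g\n",
              if (!is.null(x$measurement)) paste0(" [", x$measurement, "]")
              else "", x$method, x$statistic, x$p_value))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat("Tukey HSD adjusted p-values:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}

#' Draw synthetic per-cell stability-index tables
#'
#' Statistical-calibration generator: each cell contributes a stability index
#' formed as a binomial draw, `stable / n_events` with
#' `n_events ~ 1 + Poisson(mean_events - 1)` and
#' `stable ~ Binomial(n_events, p)`, where `p` is the group's true index.
#' This reproduces the discreteness and heteroscedasticity of real per-cell
#' indices without imaging.
#'
#' @param group_means Named numeric vector of true per-group stability
#'   indices.
#' @param n_per_group Cells per group.
#' @param mean_events Mean number of extension events per cell (default 10).
#' @return A [group_table()] (one synthetic animal per group).
#' @export
simulate_si_table <- function(group_means, n_per_group, mean_events = 10) {
  stopifnot(length(group_means) >= 2L, !is.null(names(group_means)))
  rows <- lapply(names(group_means), function(g) {
    k <- 1L + rpois(n_per_group, mean_events - 1)
    s <- rbinom(n_per_group, k, group_means[[g]])
    data.frame(group = g, animal_id = paste0(g, "_1"),
               cell_id = seq_len(n_per_group), value = s / k)
  })
  df <- do.call(rbind, rows)
  group_table(df$group, df$animal_id, df$cell_id, df$value,
              measurement = "stability_index", units = "ratio")
}

#' Write endpoint tables, comparisons and run metadata
#'
#' Emits one tidy CSV per endpoint (one row per cell), a comparisons CSV with
#' test statistics and Tukey-adjusted p-values, and a JSON metadata file
#' capturing the configuration, seed and package version. Output is
#' deterministic: re-running with the same inputs reproduces byte-identical
#' CSVs.
#'
#' @param tables Named list of [group_table()]s (e.g. `stability_index`,
#'   `soma_perimeter_um`, `cup_area_um2`, `process_length_um`).
#' @param comparisons Named list of [compare_groups()] results (may be
#'   empty).
#' @param outdir Output directory (created if needed).
#' @param config Optional configuration list echoed into the metadata.
#' @param seed Optional seed echoed into the metadata.
#' @return Invisibly, the vector of files written.
#' @export
build_report <- function(tables, comparisons = list(), outdir,
                         config = NULL, seed = NULL) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop(sprintf("cannot create output directory '%s'", outdir),
           call. = FALSE)
  written <- character(0)
  if (length(tables) == 0L)
    warning("no endpoint tables supplied; writing metadata only")
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    write.csv(as.data.frame(tables[[nm]]), f, row.names = FALSE)
    written <- c(written, f)
  }
  if (length(comparisons)) {
    rows <- lapply(names(comparisons), function(nm) {
      cp <- comparisons[[nm]]
      data.frame(measurement = nm, method = cp$method,
                 statistic = cp$statistic, p_value = cp$p_value)
    })
    f <- file.path(outdir, "comparisons.csv")
    write.csv(do.call(rbind, rows), f, row.names = FALSE)
    written <- c(written, f)
    tk <- lapply(names(comparisons), function(nm) {
      cp <- comparisons[[nm]]
      if (is.null(cp$tukey)) return(NULL)
      cbind(data.frame(measurement = nm), cp$tukey)
    })
    tk <- do.call(rbind, tk[!vapply(tk, is.null, logical(1))])
    if (!is.null(tk) && nrow(tk)) {
      f <- file.path(outdir, "tukey.csv")
      write.csv(tk, f, row.names = FALSE)
      written <- c(written, f)
    }
  }
  meta <- list(package = "microMotility",
               version = as.character(packageVersion("microMotility")),
               seed = seed,
               config = config,
               endpoints = names(tables))
  f <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  written <- c(written, f)
  invisible(written)
}
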