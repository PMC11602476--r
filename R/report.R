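#' MAD-based outlier filter
#'
#' Excludes values whose absolute deviation from the sample median exceeds
#' `k` times the normal-consistent median absolute deviation
#' (1.4826 * MAD). When the MAD is zero (more than half the values tied at
#' the median) nothing is excluded and the result is flagged.
#'
#' @param values numeric vector, length >= 3.
#' @param k cutoff multiplier (default 3).
#' @return list with `kept`, `excluded` (value vectors), `kept_idx`,
#'   `excluded_idx`, and `zero_mad` flag.
#' @export
#' @examples
#' mad_outlier_filter(c(500, 505, 510, 2000))$excluded # 2000
mad_outlier_filter <- function(values, k = 3) {
  stopifnot(length(values) >= 3)
  m <- median(values)
  s <- mad(values) # includes the 1.4826 consistency constant
  if (s == 0) {
    return(list(kept = values, excluded = numeric(0),
                kept_idx = seq_along(values), excluded_idx = integer(0),
                zero_mad = TRUE))
  }
  out <- abs(values - m) > k * s
  list(kept = values[!out], excluded = values[out],
       kept_idx = which(!out), excluded_idx = which(out),
       zero_mad = FALSE)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test with the standard zero-discard
#' convention. For small samples the exact null distribution is used:
#' via the classical recursion when the nonzero differences have untied
#' absolute values, and by full enumeration of the 2^n sign assignments
#' (midranks for ties) otherwise, so the canonical constant-shift case is
#' exact too — seven all-positive differences give p = 2/128 = 0.015625.
#' Larger samples fall back to the normal approximation with continuity
#' correction.
#'
#' @param x,y paired numeric vectors of equal length, n >= 5.
#' @param exact_max largest effective n for which the exact distribution is
#'   used (default 14).
#' @return list with `p_value`, `statistic` (V, sum of positive-difference
#'   ranks), `n_effective` (pairs after zero discard), `exact`, and
#'   `degenerate` (TRUE when all differences are zero; `p_value` is then
#'   NA).
#' @export
paired_signed_rank <- function(x, y, exact_max = 14) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p_value = NA_real_, statistic = NA_real_,
                n_effective = 0L, exact = NA, degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  use_exact <- n <= exact_max
  if (use_exact && !ties) {
    p <- wilcox.test(d, alternative = "two.sided", exact = TRUE)$p.value
  } else if (use_exact) {
    # enumerate all sign assignments of the midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(v_all >= v), mean(v_all <= v)))
  } else {
    p <- suppressWarnings(
      wilcox.test(d, alternative = "two.sided", exact = FALSE,
                  correct = TRUE)$p.value)
  }
  list(p_value = p, statistic = v, n_effective = n,
       exact = use_exact, degenerate = FALSE)
}

#' Reaction-time summary with MAD outlier exclusion
#'
#' Per-condition median, mean and SD of reaction times after
#' [mad_outlier_filter()].
#'
#' @param rt data.frame with columns `condition` and `rt_ms`.
#' @param k MAD cutoff multiplier (default 3).
#' @return data.frame of class `rt_summary` with columns `condition`,
#'   `median_ms`, `mean_ms`, `sd_ms`, `n_kept`, `n_excluded`.
#' @export
rt_summary <- function(rt, k = 3) {
  stopifnot(all(c("condition", "rt_ms") %in% names(rt)))
  rows <- lapply(split(rt$rt_ms, rt$condition), function(v) {
    f <- mad_outlier_filter(v, k)
    data.frame(median_ms = median(f$kept), mean_ms = mean(f$kept),
               sd_ms = sd(f$kept), n_kept = length(f$kept),
               n_excluded = length(f$excluded))
  })
  out <- cbind(condition = names(rows), do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("rt_summary", "data.frame")
  out
}

# full-precision numeric formatting so CSV round-trips are exact
.fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a latency table to CSV
#'
#' Numeric columns are written with 17 significant digits so re-parsing
#' reproduces the table exactly.
#'
#' @param lt a `latency_table` (see [build_latency_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly; `read_latency_table` returns the parsed
#'   `latency_table`.
#' @export
write_latency_table <- function(lt, path) {
  df <- data.frame(roi = lt$roi, condition = lt$condition,
                   mean_ms = .fmt17(lt$mean_ms), sd_ms = .fmt17(lt$sd_ms),
                   median_ms = .fmt17(lt$median_ms), n = lt$n,
                   formatted = lt$formatted)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_latency_table
#' @export
read_latency_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(mean_ms = "character", sd_ms = "character",
                                median_ms = "character"))
  out <- data.frame(roi = df$roi, condition = df$condition,
                    mean_ms = as.numeric(df$mean_ms),
                    sd_ms = as.numeric(df$sd_ms),
                    median_ms = as.numeric(df$median_ms),
                    n = as.integer(df$n), formatted = df$formatted)
  class(out) <- c("latency_table", "data.frame")
  out
}

#' Render analysis outputs to report files
#'
#' Writes the supplied result objects to `out_dir`: `latencies.csv` and
#' `latencies.json` (one entry per latency table), `rts.csv`,
#' `decoding.csv` (stacked curves with centroid, accuracy, p, significance)
#' and a Markdown `report.md` with "Mean ± SD (Median)" cells. Sections for
#' absent inputs are omitted.
#'
#' @param latency_tables named list of `latency_table` objects (or NULL).
#' @param rt_summary an [rt_summary()] data.frame (or NULL).
#' @param decoding_curves named list of `decoding_curve` objects (or NULL).
#' @param out_dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
render_tables <- function(latency_tables = NULL, rt_summary = NULL,
                          decoding_curves = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character(0)
  md <- c("# Onset-latency analysis report", "")

  if (!is.null(latency_tables) && length(latency_tables) > 0) {
    stacked <- do.call(rbind, lapply(names(latency_tables), function(nm) {
      lt <- latency_tables[[nm]]
      cbind(table = nm, as.data.frame(lt))
    }))
    p <- file.path(out_dir, "latencies.csv")
    df <- stacked
    for (col in c("mean_ms", "sd_ms", "median_ms")) df[[col]] <- .fmt17(df[[col]])
    write.csv(df, p, row.names = FALSE)
    files <- c(files, p)
    pj <- file.path(out_dir, "latencies.json")
    jsonlite::write_json(latency_tables, pj, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, pj)
    for (nm in names(latency_tables)) {
      lt <- latency_tables[[nm]]
      md <- c(md, sprintf("## Onset latencies: %s", nm), "",
              "Across-subjects onset latency means ± SDs (Medians), ms.", "",
              "| ROI | Condition | Mean ± SD (Median) | n |",
              "|---|---|---|---|",
              sprintf("| %s | %s | %s | %d |", lt$roi, lt$condition,
                      lt$formatted, lt$n),
              "")
    }
  }

  if (!is.null(rt_summary)) {
    p <- file.path(out_dir, "rts.csv")
    write.csv(rt_summary, p, row.names = FALSE)
    files <- c(files, p)
    md <- c(md, "## Reaction times (MAD outliers excluded)", "",
            "| Condition | Median (ms) | Mean ± SD (ms) | kept | excluded |",
            "|---|---|---|---|---|",
            sprintf("| %s | %d | %d ± %d | %d | %d |",
                    rt_summary$condition, round(rt_summary$median_ms),
                    round(rt_summary$mean_ms), round(rt_summary$sd_ms),
                    rt_summary$n_kept, rt_summary$n_excluded),
            "")
  }

  if (!is.null(decoding_curves) && length(decoding_curves) > 0) {
    stacked <- do.call(rbind, lapply(names(decoding_curves), function(nm) {
      cv <- decoding_curves[[nm]]
      data.frame(curve = nm, centroid_ms = cv$centroids_ms,
                 accuracy = cv$accuracy, p_value = cv$p_values,
                 significant = cv$fdr_mask)
    }))
    p <- file.path(out_dir, "decoding.csv")
    write.csv(stacked, p, row.names = FALSE)
    files <- c(files, p)
    md <- c(md, "## Temporal-searchlight decoding", "",
            "| Contrast | Windows | Mean accuracy | First significant (ms) |",
            "|---|---|---|---|",
            vapply(names(decoding_curves), function(nm) {
              cv <- decoding_curves[[nm]]
              sprintf("| %s | %d | %.3f | %s |", nm, length(cv$accuracy),
                      mean(cv$accuracy),
                      if (is.na(cv$first_significant_ms)) "none"
                      else sprintf("%.1f", cv$first_significant_ms))
            }, character(1)),
            "")
  }

  pm <- file.path(out_dir, "report.md")
  writeLines(md, pm)
  files <- c(files, pm)
  invisible(files)
}
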