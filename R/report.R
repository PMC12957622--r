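#' Descriptive table of stage distributions and I3M summaries
#'
#' Session-1 counts and percentages per (method, tooth, stage) including
#' the NA row, plus median and quartiles for continuous methods — the
#' standard first table of a staging reliability study.
#'
#' @param table A `rating_table`.
#' @param session Session to describe (default 1).
#' @return List with `stages` (method, tooth, stage, n, pct) and
#'   `continuous` (method, tooth, n, median, q1, q3, na_n, na_pct).
#' @export
describe_ratings <- function(table, session = 1L) {
  schemes <- attr(table, "schemes")
  df <- table[table$session == session, , drop = FALSE]
  stage_rows <- list()
  cont_rows <- list()
  for (m in sort(unique(df$method))) {
    sc <- schemes[[m]]
    for (t in sort(intersect(unique(df$tooth[df$method == m]),
                             sc$applicable_teeth))) {
      v <- df$value[df$method == m & df$tooth == t]
      n_total <- length(v)
      if (sc$is_continuous) {
        x <- as.numeric(v[!is.na(v)])
        qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
        cont_rows[[length(cont_rows) + 1L]] <- data.frame(
          method = m, tooth = t, n = length(x), median = qs[2],
          q1 = qs[1], q3 = qs[3], na_n = sum(is.na(v)),
          na_pct = round(100 * mean(is.na(v)), 1),
          stringsAsFactors = FALSE)
      } else {
        cnt <- table(factor(v, sc$categories), useNA = "no")
        stage_rows[[length(stage_rows) + 1L]] <- data.frame(
          method = m, tooth = t,
          stage = c(sc$categories, "NA"),
          n = c(as.integer(cnt), sum(is.na(v))),
          pct = round(100 * c(as.integer(cnt), sum(is.na(v))) / n_total,
                      1),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(stages = do.call(rbind, stage_rows),
       continuous = do.call(rbind, cont_rows))
}

inter_row <- function(label, fit) {
  if (inherits(fit, "icc_result")) {
    data.frame(
      level = label, statistic = "ICC(A,1)",
      coefficient = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
      n_observations = fit$n_subjects * fit$k_raters,
      p_value = fit$p_value,
      benchmark = benchmark_label(fit$icc, "portney_watkins"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      level = label, statistic = fit$method,
      coefficient = fit$coefficient, ci_low = fit$ci_low,
      ci_high = fit$ci_high, n_observations = fit$n_observations,
      p_value = fit$p_value,
      benchmark = benchmark_label(fit$coefficient, "landis_koch"),
      stringsAsFactors = FALSE)
  }
}

#' Run the full study analysis
#'
#' Orchestrates the reliability pipeline on a validated two-session
#' rating table:
#' \itemize{
#' \item descriptives (session-1 stage distributions, I3M summaries);
#' \item intra-observer reliability per observer and tooth: weighted
#'   Cohen's kappa for the staging methods, absolute-agreement ICC for
#'   I3M, from the session-1/session-2 pairs;
#' \item inter-observer reliability from session 1 only: Gwet's AC2 with
#'   `weights_kind` weights (category exclusion applied per analyzed
#'   matrix) for the staging methods, ICC for I3M, at Overall /
#'   Maxillary / Mandibular / per-tooth pooling levels (maxillary rows
#'   only for four-tooth methods);
#' \item NA concordance: unweighted AC1 on the binary assessability
#'   recoding of session-1 data, with the 5% prevalence audit.
#' }
#'
#' @param table A `rating_table` with both sessions.
#' @param weights_kind Weight kind for AC2 and intra-observer kappa
#'   (default `"ordinal"`).
#' @param inter_session Session used for inter-observer analyses
#'   (default 1, the initial evaluations).
#' @return Object of class `study_report` with elements `descriptives`,
#'   `intra`, `inter`, `na_table`, `provenance`.
#' @export
run_study_analysis <- function(table, weights_kind = "ordinal",
                               inter_session = 1L) {
  schemes <- attr(table, "schemes")
  methods <- intersect(names(schemes), unique(table$method))
  observers <- sort(unique(table$observer_id))
  # --- intra-observer -------------------------------------------------
  intra_rows <- list()
  has_two_sessions <- all(c(1L, 2L) %in% table$session)
  if (has_two_sessions) {
    for (m in methods) {
      sc <- schemes[[m]]
      for (t in sc$applicable_teeth) {
        for (obs in observers) {
          pr <- session_pairs(table, obs, m, t)
          if (sc$is_continuous) {
            fit <- icc_intra(pr[pr$complete, ])
            row <- data.frame(
              observer = obs, method = m, tooth = t,
              statistic = "ICC(A,1)", coefficient = fit$icc,
              ci_low = fit$ci_low, ci_high = fit$ci_high,
              n_pairs = fit$n_subjects,
              benchmark = benchmark_label(fit$icc, "portney_watkins"),
              stringsAsFactors = FALSE)
          } else {
            fit <- cohen_kappa_weighted(
              pr[pr$complete, ], scheme_categories = sc$categories,
              kind = weights_kind)
            row <- data.frame(
              observer = obs, method = m, tooth = t,
              statistic = "Cohen kappa (weighted)",
              coefficient = fit$coefficient, ci_low = fit$ci_low,
              ci_high = fit$ci_high, n_pairs = fit$n_units,
              benchmark = benchmark_label(fit$coefficient,
                                          "landis_koch"),
              stringsAsFactors = FALSE)
          }
          intra_rows[[length(intra_rows) + 1L]] <- row
        }
      }
    }
  }
  # --- inter-observer (session 1) ------------------------------------
  inter <- list()
  na_rows <- list()
  for (m in methods) {
    sc <- schemes[[m]]
    rows <- list()
    levels <- list(Overall = list(pooling = "overall"))
    if (length(intersect(c(18L, 28L), sc$applicable_teeth)) == 2L) {
      levels$Maxillary <- list(pooling = "maxillary")
    }
    if (length(intersect(c(38L, 48L), sc$applicable_teeth)) == 2L &&
        length(sc$applicable_teeth) > 2L) {
      levels$Mandibular <- list(pooling = "mandibular")
    }
    for (t in sc$applicable_teeth) {
      levels[[paste0("FDI ", t)]] <- list(teeth = t)
    }
    for (nm in names(levels)) {
      lv <- levels[[nm]]
      mat <- pivot_to_matrix(table, m, session = inter_session,
                             pooling = lv$pooling %||% "overall",
                             teeth = lv$teeth)
      fit <- if (sc$is_continuous) {
        icc_absolute(mat)
      } else {
        gwet_ac(mat, build_weights(observed_categories(mat),
                                   weights_kind))
      }
      rows[[length(rows) + 1L]] <- inter_row(nm, fit)
    }
    inter[[m]] <- do.call(rbind, rows)
    # --- NA concordance table -----------------------------------------
    na_levels <- list(Overall = "overall")
    if (length(sc$applicable_teeth) == 4L) {
      na_levels$Maxillary <- "maxillary"
      na_levels$Mandibular <- "mandibular"
    }
    for (nm in names(na_levels)) {
      mat <- pivot_to_matrix(table, m, session = inter_session,
                             pooling = na_levels[[nm]])
      rep <- na_agreement(mat)
      na_rows[[length(na_rows) + 1L]] <- data.frame(
        method = m, level = nm,
        coefficient = rep$ac1$coefficient,
        ci_low = rep$ac1$ci_low, ci_high = rep$ac1$ci_high,
        n_observations = length(mat$values),
        na_count = rep$na_count,
        na_pct = round(100 * rep$na_proportion, 1),
        p_value = rep$ac1$p_value,
        prevalence_flag = rep$prevalence_flag,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(
      descriptives = describe_ratings(table, inter_session),
      intra = if (length(intra_rows) > 0) do.call(rbind, intra_rows),
      inter = inter,
      na_table = do.call(rbind, na_rows),
      provenance = list(
        package_version = as.character(
          utils::packageVersion("dentagree")),
        weights_kind = weights_kind, inter_session = inter_session,
        n_observers = length(observers),
        assumptions = c(
          "inter-observer uses the initial session only",
          "category exclusion applied per analyzed matrix",
          "NA responses excluded observation-wise for staging agreement",
          "NA concordance uses all cells after binary recoding"))),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (m in names(x$inter)) {
    r <- x$inter[[m]][x$inter[[m]]$level == "Overall", ]
    cat(sprintf("  %s inter-observer %s: %.3f [%.3f; %.3f] (n=%d)\n",
                m, r$statistic, r$coefficient, r$ci_low, r$ci_high,
                r$n_observations))
  }
  cat(sprintf("  NA concordance rows: %d; intra rows: %d\n",
              nrow(x$na_table),
              if (is.null(x$intra)) 0L else nrow(x$intra)))
  invisible(x)
}

round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1)) &
    !(names(df) %in% c("n", "n_pairs", "n_observations", "na_count",
                       "observer", "tooth"))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

df_to_markdown <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Serialize a study report
#'
#' Deterministic output: coefficients rounded to 3 decimals and
#' percentages to 1 decimal (as conventionally printed), in CSV, JSON
#' and/or markdown.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json", "markdown")`.
#' @return Character vector of files written, invisibly.
#' @export
format_tables <- function(report, dir,
                          formats = c("csv", "json", "markdown")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pieces <- list(
    descriptives_stages = report$descriptives$stages,
    descriptives_continuous = round_df(report$descriptives$continuous),
    intra = if (!is.null(report$intra)) round_df(report$intra),
    na_table = round_df(report$na_table)
  )
  for (m in names(report$inter)) {
    pieces[[paste0("inter_", m)]] <- round_df(report$inter[[m]])
  }
  pieces <- Filter(Negate(is.null), pieces)
  written <- character(0)
  for (nm in names(pieces)) {
    if ("csv" %in% formats) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(pieces[[nm]], f, row.names = FALSE)
      written <- c(written, f)
    }
    if ("markdown" %in% formats) {
      f <- file.path(dir, paste0(nm, ".md"))
      writeLines(df_to_markdown(pieces[[nm]]), f)
      written <- c(written, f)
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(
      c(pieces, list(provenance = report$provenance)), f,
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
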