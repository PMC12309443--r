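#' Mixed-effects fit with a likelihood-ratio test of one fixed effect
#'
#' Fits, by maximum likelihood (not REML), a linear mixed model with one
#' fixed effect and nested random intercepts, plus the null model with the
#' identical random structure and the fixed effect removed, and tests the
#' fixed effect with a chi-square likelihood-ratio test on 1 df. Random
#' slopes for the fixed effect can be requested at the penguin and song
#' levels (intercepts retained). Grouping factors with fewer than 2 observed
#' levels are dropped from the random structure with a message. Singular
#' random-effects fits are kept (with a warning); the LR statistic is
#' clamped at zero if the null refit attains a numerically higher
#' likelihood.
#'
#' @param data data frame of observation rows.
#' @param response,fixed column names (character scalars).
#' @param grouping character vector of grouping columns, outermost first
#'   (e.g. `c("colony_id", "penguin_id", "song_id")`); successive columns are
#'   nested by interaction.
#' @param random_slope logical; random slopes for `fixed` at every grouping
#'   level below the first.
#' @param name label stored on the result.
#' @return object of class `"model_fit"`: a list with `name`, `estimate`,
#'   `se`, `chi_square`, `df`, `p_value`, `n`, `random_structure`,
#'   `converged`, `singular`, and the two fitted models (`full`, `null`).
#' @export
fit_lmm_lrt <- function(data, response, fixed, grouping,
                        random_slope = FALSE, name = response) {
  data <- data[is.finite(data[[response]]) & is.finite(data[[fixed]]), ,
               drop = FALSE]
  if (nrow(data) < 10L) stop("too few observations (", nrow(data), ")",
                             call. = FALSE)
  terms <- character(0)
  for (k in seq_along(grouping)) {
    g <- paste(grouping[seq_len(k)], collapse = ":")
    n_lev <- nrow(unique(data[grouping[seq_len(k)]]))
    if (n_lev < 2L) {
      message("dropping random term for '", g, "': fewer than 2 levels")
      next
    }
    inner <- if (random_slope && k > 1L) paste("1 +", fixed) else "1"
    terms <- c(terms, paste0("(", inner, " | ", g, ")"))
  }
  if (length(terms) == 0L) stop("no usable grouping factors", call. = FALSE)
  re <- paste(terms, collapse = " + ")
  f_full <- stats::as.formula(paste(response, "~", fixed, "+", re))
  f_null <- stats::as.formula(paste(response, "~ 1 +", re))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_one <- function(f) {
    withCallingHandlers(
      lme4::lmer(f, data = data, REML = FALSE, control = ctrl),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  full <- fit_one(f_full)
  null <- fit_one(f_null)
  conv <- length(full@optinfo$conv$lme4) == 0L &&
    length(null@optinfo$conv$lme4) == 0L
  singular <- lme4::isSingular(full)
  if (singular) warning("singular random-effects fit in '", name, "'",
                        call. = FALSE)
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(null))))
  coefs <- summary(full)$coefficients
  structure(list(name = name,
                 formula = paste(deparse(f_full), collapse = " "),
                 estimate = unname(coefs[fixed, "Estimate"]),
                 se = unname(coefs[fixed, "Std. Error"]),
                 chi_square = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 n = nrow(data),
                 random_structure = re,
                 converged = conv, singular = singular,
                 full = full, null = null),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s\n  %s\n  estimate = %.4f (SE %.4f), chi2(%d) = %.3f, p %s, n = %d\n",
              x$name, x$formula, x$estimate, x$se, x$df, x$chi_square,
              format.pval(x$p_value, digits = 3), x$n))
  if (!x$converged) cat("  [did not converge]\n")
  invisible(x)
}

SONG_NESTING <- c("colony_id", "penguin_id", "song_id")
PENGUIN_NESTING <- c("colony_id", "penguin_id")

#' Accelerando model: log IOI against relative position
#'
#' `ln(IOI) ~ relative position`, random intercepts for song in penguin in
#' colony. A negative slope means later IOIs are shorter (accelerando); a
#' linear slope in log space corresponds to an exponential tempo curve, so
#' `100 * (exp(slope) - 1)` is the percent change in IOI duration across the
#' whole song.
#'
#' @param intervals interval table from [dataset_intervals()].
#' @return a `"model_fit"` with an extra `percent_change` component.
#' @export
model_accelerando <- function(intervals) {
  intervals$log_ioi <- log(intervals$ioi)
  fit <- fit_lmm_lrt(intervals, "log_ioi", "relative_position", SONG_NESTING,
                     name = "accelerando: log IOI ~ relative position")
  fit$percent_change <- 100 * (exp(fit$estimate) - 1)
  fit
}

#' Acceleration-constancy model: ratio against relative position
#'
#' `acceleration ratio ~ relative position of the ratio`, random intercepts
#' for song in penguin in colony. A zero slope means the acceleration is
#' constant along the song; negative means weaker acceleration near the end.
#'
#' @param dataset a `song_dataset`.
#' @param include_c forwarded to [dataset_intervals()].
#' @return a `"model_fit"`.
#' @export
model_acceleration_constancy <- function(dataset, include_c = FALSE) {
  tab <- dataset_ratios(dataset, include_c = include_c)
  fit_lmm_lrt(tab, "ratio", "relative_position", SONG_NESTING,
              name = "acceleration constancy: ratio ~ relative position")
}

#' Per-ratio table for a dataset
#'
#' One row per acceleration ratio with its relative position
#' (`(i-1)/(n-3)` for a song of n retained syllables). Songs with fewer than
#' 4 retained syllables (fewer than 2 IOIs after truncation) contribute
#' nothing.
#'
#' @inheritParams model_acceleration_constancy
#' @return data frame `colony_id`, `penguin_id`, `song_id`, `index`,
#'   `ratio`, `relative_position`.
#' @export
dataset_ratios <- function(dataset, include_c = FALSE) {
  songs <- split_songs(dataset)
  out <- lapply(songs, function(s) {
    iv <- tryCatch(compute_intervals(s, include_c = include_c),
                   error = function(e) NULL)
    if (is.null(iv) || nrow(iv) < 2L) return(NULL)
    r <- acceleration_ratios(iv$ioi)
    data.frame(colony_id = iv$colony_id[1L], penguin_id = iv$penguin_id[1L],
               song_id = iv$song_id[1L], index = seq_along(r), ratio = r,
               relative_position = if (length(r) >= 2L)
                 relative_positions(length(r)) else 0.5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

#' Component-duration models: log syllable and log silence
#'
#' Two mixed models with fixed effect = the IOI's relative position and
#' random intercepts for song in penguin in colony: one for
#' `ln(syllable duration)`, one for `ln(silence)`. Zero-length silences
#' cannot enter the log model and are excluded with a logged count. Percent
#' changes over the whole song (`100 * (exp(slope) - 1)`) are attached.
#'
#' @param intervals interval table from [dataset_intervals()].
#' @return list with `"model_fit"` components `syllable` and `silence`.
#' @export
model_component_durations <- function(intervals) {
  intervals$log_syl <- log(intervals$syllable_duration)
  syl <- fit_lmm_lrt(intervals, "log_syl", "relative_position", SONG_NESTING,
                     name = "syllable duration: log duration ~ relative position")
  syl$percent_change <- 100 * (exp(syl$estimate) - 1)
  n_zero <- sum(intervals$silence <= 0)
  if (n_zero > 0L) {
    message(n_zero, " zero-length silence(s) excluded from the log-silence model")
  }
  sil_tab <- intervals[intervals$silence > 0, , drop = FALSE]
  sil_tab$log_sil <- log(sil_tab$silence)
  sil <- fit_lmm_lrt(sil_tab, "log_sil", "relative_position", SONG_NESTING,
                     name = "silence duration: log silence ~ relative position")
  sil$percent_change <- 100 * (exp(sil$estimate) - 1)
  list(syllable = syl, silence = sil)
}

#' IOI-variability trend: binned CV against bin position
#'
#' `corrected CV ~ bin position`, random intercepts for penguin in colony,
#' over the five-bin-per-penguin CV table. A negative slope means songs get
#' more precise (less variable IOIs) towards the end.
#'
#' @param binned output of [bin_iois()]; undefined bins (`NA` CV) dropped.
#' @return a `"model_fit"`.
#' @export
model_cv_trend <- function(binned) {
  tab <- binned[is.finite(binned$cv), , drop = FALSE]
  fit_lmm_lrt(tab, "cv", "bin_position", PENGUIN_NESTING,
              name = "IOI variability: binned CV ~ bin position")
}

#' Song-level table: first IOI and average acceleration
#'
#' One row per song with a defined average acceleration ratio (at least 5
#' retained syllables): the first IOI's duration and the mean of the
#' remaining acceleration ratios (excluding the one involving the first
#' IOI).
#'
#' @inheritParams model_acceleration_constancy
#' @return data frame `colony_id`, `penguin_id`, `song_id`, `ioi1`,
#'   `avg_accel`, `n_syllables`.
#' @export
dataset_song_summary <- function(dataset, include_c = FALSE) {
  songs <- split_songs(dataset)
  out <- lapply(songs, function(s) {
    iv <- tryCatch(compute_intervals(s, include_c = include_c),
                   error = function(e) NULL)
    if (is.null(iv) || nrow(iv) < 3L) return(NULL)
    r <- acceleration_ratios(iv$ioi)
    if (length(r) < 2L) return(NULL)
    data.frame(colony_id = iv$colony_id[1L], penguin_id = iv$penguin_id[1L],
               song_id = iv$song_id[1L], ioi1 = iv$ioi[1L],
               avg_accel = average_acceleration(r),
               n_syllables = nrow(iv) + 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

#' Tempo-plasticity model: average acceleration against the first IOI
#'
#' `average acceleration ratio ~ IOI_1 duration`, random intercepts for
#' penguin in colony. Because penguin identity is in the random structure,
#' the fixed effect captures within-penguin plasticity: a positive slope
#' means a song that starts slow (long first IOI) accelerates more strongly.
#'
#' @inheritParams model_acceleration_constancy
#' @return a `"model_fit"`.
#' @export
model_ioi1_plasticity <- function(dataset, include_c = FALSE) {
  tab <- dataset_song_summary(dataset, include_c = include_c)
  fit_lmm_lrt(tab, "avg_accel", "ioi1", PENGUIN_NESTING,
              name = "tempo plasticity: average acceleration ~ IOI1")
}

#' Crescendo model: normalized intensity against syllable position
#'
#' `intensity relative to the first B syllable ~ relative syllable
#' position`, with random slopes for position at the penguin and song levels
#' (intercepts retained) and a random intercept for colony. A positive slope
#' (dB per unit position) is a crescendo. If the random-slope fit fails or
#' both slope variances collapse to zero, the model is downgraded to nested
#' random intercepts with a message.
#'
#' @param dataset a `song_dataset` with intensities on egressive syllables.
#' @param include_b include the B syllable (position 1, normalized 0 dB) as
#'   an observation? Default `TRUE`.
#' @return a `"model_fit"`.
#' @export
model_crescendo <- function(dataset, include_b = TRUE) {
  songs <- split_songs(dataset)
  tab <- lapply(songs, function(s) {
    ni <- tryCatch(normalize_intensity(s), error = function(e) NULL)
    if (is.null(ni) || nrow(ni) < 3L) return(NULL)
    cbind(s[1L, c("colony_id", "penguin_id", "song_id")], ni,
          row.names = NULL)
  })
  tab <- tab[!vapply(tab, is.null, logical(1))]
  if (length(tab) == 0L) {
    stop("no songs with complete egressive intensities: cannot fit the ",
         "crescendo model", call. = FALSE)
  }
  tab <- do.call(rbind, c(tab, list(make.row.names = FALSE)))
  if (!include_b) tab <- tab[tab$label != "B", , drop = FALSE]
  fit <- tryCatch(
    fit_lmm_lrt(tab, "norm_intensity_db", "relative_position", SONG_NESTING,
                random_slope = TRUE,
                name = "crescendo: normalized intensity ~ syllable position"),
    error = function(e) NULL)
  degenerate <- is.null(fit) || !fit$converged ||
    (!is.null(fit) && all(slope_variances(fit$full, "relative_position") < 1e-10))
  if (degenerate) {
    message("random-slope crescendo fit degenerate; ",
            "downgrading to nested random intercepts")
    fit <- fit_lmm_lrt(tab, "norm_intensity_db", "relative_position",
                       SONG_NESTING, random_slope = FALSE,
                       name = "crescendo: normalized intensity ~ syllable position (intercepts)")
  }
  fit
}

slope_variances <- function(fit, term) {
  vc <- lme4::VarCorr(fit)
  v <- vapply(vc, function(m) {
    if (term %in% rownames(m)) m[term, term] else NA_real_
  }, numeric(1))
  v[!is.na(v)]
}

#' Per-penguin ordinary least-squares regressions
#'
#' Re-runs one of the suite's analyses penguin by penguin with plain OLS
#' (random effects dropped): `accelerando` (log IOI on IOI position),
#' `crescendo` (normalized intensity on syllable position) or `ioi1`
#' (average acceleration on first IOI). Penguins with fewer than `min_obs`
#' observations are skipped with a message.
#'
#' @param dataset a `song_dataset`.
#' @param analysis one of `"accelerando"`, `"crescendo"`, `"ioi1"`.
#' @param min_obs minimum observations per penguin, default 10.
#' @param alpha significance level for the directional count.
#' @param include_c forwarded to the table builders.
#' @return data frame with one row per penguin (`slope`, `se`, `p_value`,
#'   `n`) plus attributes `n_significant` (significant slopes in the
#'   analysis's expected direction) and `expected_sign`.
#' @export
per_penguin_regressions <- function(dataset,
                                    analysis = c("accelerando", "crescendo",
                                                 "ioi1"),
                                    min_obs = 10L, alpha = 0.05,
                                    include_c = FALSE) {
  analysis <- match.arg(analysis)
  spec <- switch(analysis,
    accelerando = {
      tab <- dataset_intervals(dataset, include_c = include_c)
      tab$y <- log(tab$ioi); tab$x <- tab$relative_position
      list(tab = tab, sign = -1)
    },
    crescendo = {
      songs <- split_songs(dataset)
      pieces <- lapply(songs, function(s) {
        ni <- tryCatch(normalize_intensity(s), error = function(e) NULL)
        if (is.null(ni)) return(NULL)
        cbind(s[1L, c("colony_id", "penguin_id", "song_id")], ni,
              row.names = NULL)
      })
      pieces <- pieces[!vapply(pieces, is.null, logical(1))]
      if (length(pieces) == 0L) {
        stop("no songs with complete egressive intensities", call. = FALSE)
      }
      tab <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
      tab$y <- tab$norm_intensity_db; tab$x <- tab$relative_position
      list(tab = tab, sign = +1)
    },
    ioi1 = {
      tab <- dataset_song_summary(dataset, include_c = include_c)
      tab$y <- tab$avg_accel; tab$x <- tab$ioi1
      list(tab = tab, sign = +1)
    })
  groups <- split(spec$tab, interaction(spec$tab$colony_id,
                                        spec$tab$penguin_id, drop = TRUE,
                                        sep = "\r"))
  skipped <- 0L
  rows <- lapply(groups, function(g) {
    if (nrow(g) < min_obs) { skipped <<- skipped + 1L; return(NULL) }
    fit <- stats::lm(y ~ x, data = g)
    cf <- summary(fit)$coefficients
    data.frame(colony_id = g$colony_id[1L], penguin_id = g$penguin_id[1L],
               slope = cf["x", "Estimate"], se = cf["x", "Std. Error"],
               p_value = cf["x", "Pr(>|t|)"], n = nrow(g),
               stringsAsFactors = FALSE)
  })
  if (skipped > 0L) message(skipped, " under-observed penguin(s) skipped")
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out)) {
    stop("no penguin reaches ", min_obs, " observations for the '",
         analysis, "' regression", call. = FALSE)
  }
  attr(out, "expected_sign") <- spec$sign
  attr(out, "n_significant") <- sum(out$p_value < alpha &
                                      sign(out$slope) == spec$sign)
  out
}

#' First-versus-last IOI variability per penguin
#'
#' For every penguin with at least `min_songs` eligible songs, collects the
#' first IOI and the last IOI (the one ending at the B syllable) of each
#' song and tests equality of their coefficients of variation with the
#' modified signed-likelihood ratio test ([cv_equality_test()]).
#'
#' @param dataset a `song_dataset`.
#' @param min_songs minimum songs per penguin, default 6.
#' @param alpha significance level for the decrease count.
#' @param include_c forwarded to [dataset_intervals()].
#' @param n_boot Monte-Carlo size for the test's mean correction.
#' @return data frame with one row per penguin: `cv_first`, `cv_last`,
#'   `statistic`, `p_value`, `n_songs`; attribute `n_significant_decrease`
#'   counts penguins with `cv_first > cv_last` at `p < alpha`.
#' @export
cv_equality_by_penguin <- function(dataset, min_songs = 6L, alpha = 0.05,
                                   include_c = FALSE, n_boot = 200L) {
  iv <- dataset_intervals(dataset, include_c = include_c)
  groups <- split(iv, interaction(iv$colony_id, iv$penguin_id, drop = TRUE,
                                  sep = "\r"))
  rows <- lapply(groups, function(g) {
    per_song <- split(g, g$song_id)
    firsts <- vapply(per_song, function(s) s$ioi[which.min(s$index)],
                     numeric(1))
    lasts <- vapply(per_song, function(s) s$ioi[which.max(s$index)],
                    numeric(1))
    if (length(firsts) < min_songs) return(NULL)
    tst <- cv_equality_test(firsts, lasts, n_boot = n_boot)
    data.frame(colony_id = g$colony_id[1L], penguin_id = g$penguin_id[1L],
               cv_first = corrected_cv(firsts), cv_last = corrected_cv(lasts),
               statistic = tst$statistic, p_value = tst$p_value,
               n_songs = length(firsts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  attr(out, "n_significant_decrease") <-
    sum(out$p_value < alpha & out$cv_first > out$cv_last)
  out
}
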