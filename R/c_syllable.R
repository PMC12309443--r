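#' Partition acceleration ratios by C-syllable affectedness
#'
#' Builds the three acceleration-ratio distributions that decide whether
#' ingressive C syllables take part in a song's temporal stream:
#'
#' * **baseline** — ratios computed on the egressive (A/B) onset stream whose
#'   two constituent IOIs contain no C onset;
#' * **c_omitted** — egressive-stream ratios whose span does contain a C
#'   onset (the C onset is ignored in the IOI arithmetic);
#' * **c_included** — ratios computed on the all-syllable onset stream in
#'   which at least one of the three constituent onsets is a C onset (every
#'   ratio over an affected span is included).
#'
#' A C onset "affects" an egressive ratio when it falls strictly inside one
#' of the ratio's two constituent onset-to-onset intervals (half-open
#' `[start, end)`).
#'
#' @param dataset a `song_dataset`.
#' @return list with data frames `baseline`, `c_omitted`, `c_included` (each
#'   with `colony_id`, `penguin_id`, `song_id`, `ratio`) and `c_counts`, the
#'   per-penguin count of C syllables.
#' @export
partition_ratios <- function(dataset) {
  songs <- split_songs(dataset)
  base <- om <- inc <- list()
  df <- as.data.frame(dataset)
  is_c <- df$label == "C"
  c_counts <- stats::aggregate(list(n_c = is_c),
                               by = df[c("colony_id", "penguin_id")], FUN = sum)
  for (song in songs) {
    eg <- song[song$label != "C", , drop = FALSE]
    if (nrow(eg) < 4L) next  # need two egressive IOIs to form a ratio
    e_on <- eg$onset_s
    r_eg <- acceleration_ratios(diff(e_on))
    c_on <- song$onset_s[song$label == "C"]
    affected <- vapply(seq_along(r_eg), function(i) {
      any(c_on >= e_on[i] & c_on < e_on[i + 2L])
    }, logical(1))
    ids <- song[1L, c("colony_id", "penguin_id", "song_id")]
    mk <- function(r) if (length(r)) cbind(ids, ratio = r,
                                           row.names = NULL) else NULL
    base[[length(base) + 1L]] <- mk(r_eg[!affected])
    om[[length(om) + 1L]] <- mk(r_eg[affected])
    if (length(c_on) > 0L && nrow(song) >= 4L) {
      a_on <- song$onset_s
      r_all <- acceleration_ratios(diff(a_on))
      c_flag <- song$label == "C"
      with_c <- vapply(seq_along(r_all), function(i) {
        any(c_flag[i:(i + 2L)])
      }, logical(1))
      inc[[length(inc) + 1L]] <- mk(r_all[with_c])
    }
  }
  bind <- function(lst) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (length(lst) == 0L) {
      return(data.frame(colony_id = character(), penguin_id = character(),
                        song_id = character(), ratio = numeric(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  list(baseline = bind(base), c_omitted = bind(om), c_included = bind(inc),
       c_counts = c_counts)
}

#' Gaussian kernel density estimate of the baseline ratios
#'
#' Fits a Gaussian KDE (Silverman's rule-of-thumb bandwidth by default) that
#' can be evaluated at arbitrary points via [kde_eval()]. The density is an
#' equal-weight mixture of normals, so it is nonnegative and integrates to 1
#' exactly.
#'
#' @param ratios baseline acceleration ratios, at least 10.
#' @param bandwidth kernel SD; default `stats::bw.nrd0(ratios)`.
#' @return object of class `"gaussian_kde"`.
#' @export
baseline_kde <- function(ratios, bandwidth = NULL) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 10L) {
    stop("baseline KDE needs at least 10 ratios, got ", length(ratios),
         call. = FALSE)
  }
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(ratios)
  structure(list(sample = ratios, bandwidth = bandwidth),
            class = "gaussian_kde")
}

#' Evaluate a Gaussian KDE
#'
#' @param kde a `"gaussian_kde"` from [baseline_kde()].
#' @param x points at which to evaluate the density.
#' @return density values, same length as `x`.
#' @export
kde_eval <- function(kde, x) {
  stopifnot(inherits(kde, "gaussian_kde"))
  vapply(x, function(q) mean(stats::dnorm(q, kde$sample, kde$bandwidth)),
         numeric(1))
}

#' Compare C-omitted and C-included ratios against the baseline density
#'
#' Evaluates the pooled-baseline KDE likelihood of every C-omitted and
#' C-included ratio, takes per-penguin medians of the two likelihood sets,
#' and runs a paired two-sided Wilcoxon signed-rank test on the per-penguin
#' (omitted - included) differences. Only penguins with at least
#' `min_c_syllables` C syllables across their songs (and ratios in both
#' alternative distributions) are eligible. The reported `T` is the smaller
#' of the two signed-rank sums; zero differences are dropped.
#'
#' @param dists output of [partition_ratios()].
#' @param min_c_syllables eligibility threshold, default 3.
#' @param bandwidth optional KDE bandwidth forwarded to [baseline_kde()].
#' @param alpha significance level used for the verdict, default 0.05.
#' @return list with the per-penguin likelihood table, `wilcoxon_T`,
#'   `p_value`, `n_penguins`, the fitted `kde`, and a `verdict`
#'   (`"omit"`, `"include"`, or `"inconclusive"`).
#' @export
likelihood_comparison <- function(dists, min_c_syllables = 3L,
                                  bandwidth = NULL, alpha = 0.05) {
  eligible <- dists$c_counts[dists$c_counts$n_c >= min_c_syllables, ,
                             drop = FALSE]
  key <- function(d) paste(d$colony_id, d$penguin_id)
  eligible <- eligible[key(eligible) %in% key(dists$c_omitted) &
                         key(eligible) %in% key(dists$c_included), ,
                       drop = FALSE]
  if (nrow(eligible) == 0L) {
    stop(structure(class = c("eligibility_error", "error", "condition"),
                   list(message = paste("no penguin has at least",
                                        min_c_syllables,
                                        "C syllables with computable ratios"),
                        call = NULL)))
  }
  kde <- baseline_kde(dists$baseline$ratio, bandwidth = bandwidth)
  per <- lapply(seq_len(nrow(eligible)), function(i) {
    k <- key(eligible)[i]
    lo <- kde_eval(kde, dists$c_omitted$ratio[key(dists$c_omitted) == k])
    li <- kde_eval(kde, dists$c_included$ratio[key(dists$c_included) == k])
    data.frame(colony_id = eligible$colony_id[i],
               penguin_id = eligible$penguin_id[i],
               n_c = eligible$n_c[i],
               n_omitted = length(lo), n_included = length(li),
               median_lik_omitted = stats::median(lo),
               median_lik_included = stats::median(li),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  d <- per$median_lik_omitted - per$median_lik_included
  n_eff <- sum(d != 0)
  if (n_eff == 0L) {
    wt <- list(statistic = c(V = 0), p.value = 1)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(per$median_lik_omitted, per$median_lik_included,
                         paired = TRUE, exact = nrow(per) <= 25))
  }
  v <- unname(wt$statistic)
  t_small <- min(v, n_eff * (n_eff + 1) / 2 - v)
  verdict <- if (wt$p.value < alpha) {
    if (stats::median(d) > 0) "omit" else "include"
  } else "inconclusive"
  list(per_penguin = per, wilcoxon_T = t_small, wilcoxon_V = v,
       p_value = wt$p.value, n_penguins = nrow(per), kde = kde,
       verdict = verdict)
}
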