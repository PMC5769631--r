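# Group comparison of quadrant-level shortening factors: per-group,
# per-quadrant summaries (mean +/- sd) and the unpaired two-sample
# pooled-variance Student's t-test used for between-group differences.
# Welch's correction is available behind a flag; no multiple-testing
# correction is applied across quadrants (each region is reported with its
# own p value), which is noted in the output metadata.

#' Validate and normalize a shortening group table
#'
#' @param df data frame with columns `embryo`, `group`, `quadrant`
#'   (in `a`, `b`, `c`, `d`) and `shortening`.
#' @return the validated data frame (class `group_table`).
#' @export
group_table <- function(df) {
  req <- c("embryo", "group", "quadrant", "shortening")
  if (!all(req %in% names(df))) {
    stop("group table needs columns: ", paste(req, collapse = ", "))
  }
  stopifnot(all(df$quadrant %in% c("a", "b", "c", "d")))
  dup <- duplicated(df[, c("embryo", "quadrant")])
  if (any(dup)) {
    stop("one value per embryo x quadrant expected; duplicates found")
  }
  class(df) <- c("group_table", class(df))
  df
}

#' Per-group, per-quadrant mean and standard deviation
#'
#' @param df a [group_table()] (or compatible data frame).
#' @return data frame with `group`, `quadrant`, `mean`, `sd` (sample,
#'   n-1 denominator), `n`; empty cells yield `NA`.
#' @export
summarize_shortening <- function(df) {
  groups <- unique(df$group)
  quads <- c("a", "b", "c", "d")
  out <- expand.grid(group = groups, quadrant = quads,
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_
  out$sd <- NA_real_
  out$n <- 0L
  for (r in seq_len(nrow(out))) {
    v <- df$shortening[df$group == out$group[r] &
                       df$quadrant == out$quadrant[r]]
    v <- v[is.finite(v)]
    out$n[r] <- length(v)
    if (length(v) >= 1) out$mean[r] <- mean(v)
    if (length(v) >= 2) out$sd[r] <- stats::sd(v)
  }
  out
}

#' Unpaired two-sample Student's t-test (pooled variance)
#'
#' Classic pooled-variance test with `df = nA + nB - 2` and a two-tailed p
#' value; set `welch = TRUE` for the unequal-variance correction.
#' Degenerate zero-variance inputs are handled explicitly: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` flagged degenerate.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param welch use the Welch-Satterthwaite correction.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
t_test_unpaired <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  na <- length(a)
  nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  ma <- mean(a)
  mb <- mean(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va + vb == 0) {
    if (ma == mb) {
      return(list(t = 0, df = na + nb - 2, p = 1, mean_a = ma, mean_b = mb,
                  degenerate = TRUE))
    }
    return(list(t = sign(ma - mb) * Inf, df = na + nb - 2, p = 0,
                mean_a = ma, mean_b = mb, degenerate = TRUE))
  }
  if (welch) {
    se2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(se2)
    dff <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    dff <- na + nb - 2
  }
  p <- 2 * stats::pt(-abs(tt), dff)
  list(t = tt, df = dff, p = p, mean_a = ma, mean_b = mb, degenerate = FALSE)
}

#' Compare two groups per quadrant
#'
#' Runs [t_test_unpaired()] for every quadrant between two named groups.
#'
#' @param df a [group_table()].
#' @param group_a,group_b group labels to compare.
#' @param welch use Welch's correction.
#' @return data frame with one row per quadrant: means, `t`, `df`, `p`,
#'   group sizes, and metadata attribute
#'   `"multiple_testing" = "none (per-region tests reported individually)"`.
#' @export
compare_groups <- function(df, group_a, group_b, welch = FALSE) {
  quads <- c("a", "b", "c", "d")
  rows <- lapply(quads, function(q) {
    va <- df$shortening[df$group == group_a & df$quadrant == q]
    vb <- df$shortening[df$group == group_b & df$quadrant == q]
    va <- va[is.finite(va)]
    vb <- vb[is.finite(vb)]
    if (length(va) < 2 || length(vb) < 2) {
      return(data.frame(quadrant = q, mean_a = NA, mean_b = NA,
                        n_a = length(va), n_b = length(vb),
                        t = NA, df = NA, p = NA))
    }
    tt <- t_test_unpaired(va, vb, welch)
    data.frame(quadrant = q, mean_a = tt$mean_a, mean_b = tt$mean_b,
               n_a = length(va), n_b = length(vb),
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(group_a, group_b)
  attr(out, "multiple_testing") <-
    "none (per-region tests reported individually)"
  out
}
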