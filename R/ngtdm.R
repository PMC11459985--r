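# Neighbourhood grey-tone difference matrix (NGTDM): per grey level, the
# occurrence probability and the summed absolute difference between the
# level and the mean of its valid 26-neighbours (neighbours outside the
# mask are ignored).

# Per-level occurrence counts n_i and summed differences s_i.
ngtdm_table <- function(levels, ng) {
  valid <- !is.na(levels)
  num <- array(0, dim = dim(levels))
  cnt <- array(0, dim = dim(levels))
  offs <- offsets_26()
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(levels, offs[r, ])
    ok <- !is.na(nb)
    num[ok] <- num[ok] + nb[ok]
    cnt <- cnt + ok
  }
  use <- valid & cnt > 0
  diffs <- abs(levels[use] - num[use] / cnt[use])
  lv <- levels[use]
  n_i <- tabulate(lv, nbins = ng)
  s_i <- vapply(seq_len(ng), function(g) sum(diffs[lv == g]), 0)
  list(n = n_i, s = s_i, nvc = sum(use))
}

#' NGTDM features (5)
#'
#' Coarseness, contrast, busyness, complexity and strength from the
#' neighbourhood grey-tone difference table. Degenerate denominators follow
#' the usual conventions: coarseness is capped at `1e6` when its
#' denominator vanishes; contrast, busyness, complexity and strength are 0
#' for a single occupied grey level or an all-zero difference table.
#'
#' @param droi A `discretized_roi`.
#' @param coarseness_cap Value returned for coarseness when `sum(p_i s_i)`
#'   is zero.
#' @return Named numeric vector of 5 features (prefix `ngtdm_`).
#' @export
ngtdm_features <- function(droi, coarseness_cap = 1e6) {
  stopifnot(inherits(droi, "discretized_roi"))
  lev <- crop_levels(droi)
  tb <- ngtdm_table(lev, droi$ng)
  if (tb$nvc == 0) stop("empty mask")
  p <- tb$n / tb$nvc
  s <- tb$s
  gl <- seq_len(droi$ng)
  occ <- which(p > 0)
  ngp <- length(occ)

  den_coar <- sum(p * s)
  coarseness <- if (den_coar > 0) min(1 / den_coar, coarseness_cap) else coarseness_cap

  contrast <- if (ngp > 1) {
    (sum(outer(p[occ], p[occ]) * outer(gl[occ], gl[occ], "-")^2) /
       (ngp * (ngp - 1))) * (sum(s) / tb$nvc)
  } else 0

  den_busy <- sum(abs(outer(gl[occ] * p[occ], gl[occ] * p[occ], "-")))
  busyness <- if (den_busy > 0) sum(p * s) / den_busy else 0

  complexity <- if (ngp > 1) {
    ps <- p[occ] * s[occ]
    sum(abs(outer(gl[occ], gl[occ], "-")) *
          (outer(ps, ps, "+") / outer(p[occ], p[occ], "+"))) / tb$nvc
  } else 0

  strength <- if (sum(s) > 0) {
    sum(outer(p[occ], p[occ], "+") * outer(gl[occ], gl[occ], "-")^2) / sum(s)
  } else 0

  c(ngtdm_coarseness = coarseness,
    ngtdm_contrast = contrast,
    ngtdm_busyness = busyness,
    ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}
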