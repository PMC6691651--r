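#' Biologically effective dose (BED) of a fractionation scheme
#'
#' Computes the BED of a scheme of `n` fractions of `d` Gy under the basic
#' linear-quadratic model,
#' \deqn{BED = (n d) \left(1 + \frac{d}{\alpha/\beta}\right),}
#' with no time/repopulation correction. Low alpha/beta ratios (2--3 Gy)
#' describe late-responding tissue such as cerebrum; ~10 Gy describes
#' early-responding tissue and tumor.
#'
#' @param scheme a [FractionationScheme-class].
#' @param alphaBeta alpha/beta ratio in Gy; strictly positive scalar.
#' @return BED in Gy.
#' @examples
#' bed(fractionationScheme(5, 20), alphaBeta = 2)   # 1100
#' bed(fractionationScheme(10, 9), alphaBeta = 3)   # 360
#' @seealso [sfedFromBed()], [doseMetrics()], [schemeTable()]
#' @rdname bed
#' @export
setMethod("bed", "FractionationScheme", function(scheme, alphaBeta) {
  .checkAlphaBeta(alphaBeta)
  validObject(scheme)
  (scheme@n * scheme@d) * (1 + scheme@d / alphaBeta)
})

.checkAlphaBeta <- function(alphaBeta) {
  if (length(alphaBeta) != 1L || !is.finite(alphaBeta) || alphaBeta <= 0)
    stop("alphaBeta must be a strictly positive scalar (Gy), got: ",
         paste(alphaBeta, collapse = ","))
  invisible(alphaBeta)
}

#' Single-fraction equivalent dose from a BED
#'
#' Inverts the linear-quadratic relation for a single fraction: the SFED is
#' the dose that, delivered in one fraction, has the given BED. It is the
#' non-negative root of `SFED * (1 + SFED / alphaBeta) = BED`,
#' \deqn{SFED = \frac{-1 + \sqrt{1 + 4\,BED/(\alpha/\beta)}}{2/(\alpha/\beta)}.}
#'
#' @param bed biologically effective dose in Gy (non-negative).
#' @param alphaBeta alpha/beta ratio in Gy; strictly positive scalar.
#' @return SFED in Gy; vectorised over `bed`.
#' @examples
#' sfedFromBed(1100, alphaBeta = 2)  # 45.91
#' sfedFromBed(300, alphaBeta = 10)  # exactly 50
#' @export
sfedFromBed <- function(bed, alphaBeta) {
  .checkAlphaBeta(alphaBeta)
  if (any(!is.finite(bed)) || any(bed < 0))
    stop("bed must be non-negative and finite (Gy), got: ",
         paste(bed, collapse = ","))
  (-1 + sqrt(1 + 4 * bed / alphaBeta)) / (2 / alphaBeta)
}

#' BED and SFED of a scheme at one alpha/beta ratio
#'
#' Composes [bed()] and [sfedFromBed()] into a validated
#' [DoseMetrics-class] object. For a single-fraction scheme the SFED equals
#' the physical dose.
#'
#' @inheritParams bed
#' @return a [DoseMetrics-class].
#' @examples
#' doseMetrics(fractionationScheme(10, 10), alphaBeta = 2)  # BED 600, SFED 33.66
#' @rdname doseMetrics
#' @export
setMethod("doseMetrics", "FractionationScheme", function(scheme, alphaBeta) {
  b <- bed(scheme, alphaBeta)
  new("DoseMetrics", scheme = scheme, alphaBeta = as.numeric(alphaBeta),
      bed = b, sfed = sfedFromBed(b, alphaBeta))
})

#' Parse "NxD" scheme strings
#'
#' @param x character vector such as `c("5x20", "10x9")` (case-insensitive
#'   separator `x`).
#' @return a list of [FractionationScheme-class] objects.
#' @examples
#' parseSchemes(c("5x20", "1x90"))
#' @export
parseSchemes <- function(x) {
  parts <- regmatches(x, regexec("^([0-9]+)[xX]([0-9.]+)$", x))
  lapply(seq_along(x), function(i) {
    p <- parts[[i]]
    if (length(p) != 3L)
      stop("cannot parse scheme string: '", x[i], "' (expected \"NxD\")")
    fractionationScheme(as.integer(p[2]), as.numeric(p[3]), label = x[i])
  })
}

#' The four fractionation schemes of the reference study design
#'
#' 5 x 20 Gy, 10 x 10 Gy, 5 x 18 Gy and 10 x 9 Gy: two 100 Gy and two
#' 90 Gy total-dose regimens delivered in 5 or 10 daily fractions.
#'
#' @return a list of four [FractionationScheme-class] objects.
#' @export
defaultSchemes <- function() {
  parseSchemes(c("5x20", "10x10", "5x18", "10x9"))
}

.tissueClass <- function(alphaBeta) {
  ifelse(alphaBeta <= 5, "late_cerebrum", "early_tumor")
}

#' Dose-equivalence table over schemes and alpha/beta ratios
#'
#' One row per (scheme, alpha/beta) combination with fraction count, dose
#' per fraction, total dose, BED and SFED. With the default schemes and
#' alpha/beta grid \{2, 3, 10\} Gy this reproduces the full 12-row
#' dose-equivalence table of the study design: e.g. 5 x 20 Gy has BED
#' 1100 Gy and SFED 45.91 Gy at alpha/beta = 2 Gy, and SFED exactly 50 Gy
#' at alpha/beta = 10 Gy.
#'
#' @param schemes list of [FractionationScheme-class] objects (or a character
#'   vector of `"NxD"` strings).
#' @param alphaBeta numeric vector of alpha/beta ratios in Gy.
#' @return a data.frame with columns `label`, `n`, `d_Gy`, `total_Gy`,
#'   `alpha_beta_Gy`, `tissue_class`, `BED_Gy`, `SFED_Gy`.
#' @examples
#' tab <- schemeTable()
#' subset(tab, alpha_beta_Gy == 2)
#' @export
schemeTable <- function(schemes = defaultSchemes(), alphaBeta = c(2, 3, 10)) {
  if (is.character(schemes)) schemes <- parseSchemes(schemes)
  if (length(schemes) == 0L) stop("schemes must be a non-empty list")
  if (length(alphaBeta) == 0L) stop("alphaBeta must be a non-empty vector")
  rows <- lapply(alphaBeta, function(ab) {
    do.call(rbind, lapply(schemes, function(s) {
      m <- doseMetrics(s, ab)
      data.frame(label = s@label, n = s@n, d_Gy = s@d,
                 total_Gy = s@n * s@d, alpha_beta_Gy = ab,
                 tissue_class = .tissueClass(ab),
                 BED_Gy = m@bed, SFED_Gy = m@sfed,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
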