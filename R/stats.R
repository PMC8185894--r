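#' @include AllClasses.R shells.R
NULL

#' Welch two-sample t-test
#'
#' Unpaired, unequal-variance, two-tailed t-test (Welch statistic with
#' Welch-Satterthwaite degrees of freedom), the test used throughout this
#' assay for between-condition comparisons. Thin wrapper around
#' [stats::t.test()] returning a flat one-row data frame convenient for
#' binding across shells or group pairs.
#'
#' @param a,b numeric samples, each of length >= 2; at least one must
#'   have nonzero variance.
#' @param alpha significance level for the flag (default 0.05).
#' @return One-row data frame: \code{t}, \code{df}, \code{p_value},
#'   \code{significant}.
#' @examples
#' welchTest(rnorm(20), rnorm(20, 1))
#' @export
welchTest <- function(a, b, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample must contain at least 2 values")
  if (sd(a) == 0 && sd(b) == 0)
    stop("both samples are constant; the Welch statistic is undefined")
  ht <- t.test(a, b, var.equal = FALSE)
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p_value = ht$p.value, significant = ht$p.value < alpha)
}

#' Shell-wise comparison of two sets of nucleus profiles
#'
#' Welch t-test on the DAPI-normalized values of each shell between two
#' groups of nuclei; the significance flags are the ones marked as
#' asterisks on shell histograms. No multiple-testing correction is
#' applied by default; set \code{adjust = "BH"} for Benjamini-Hochberg
#' adjusted flags.
#'
#' @param a,b per-nucleus shell profiles of the two groups: data frames
#'   from [shellProfile()]/[analyzeCondition2D()] or numeric matrices of
#'   normalized values (nuclei x shells).
#' @param alpha significance level.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return Data frame with one row per shell: \code{shell}, \code{t},
#'   \code{df}, \code{p_value} (and \code{p_adjusted} when adjusting),
#'   \code{significant}.
#' @importFrom stats p.adjust
#' @export
compareShellProfiles <- function(a, b, alpha = 0.05,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ma <- profileMatrix(a)
  mb <- profileMatrix(b)
  if (ncol(ma) != ncol(mb)) stop("groups use different shell counts")
  out <- do.call(rbind, lapply(seq_len(ncol(ma)), function(k)
    cbind(shell = k, welchTest(ma[, k], mb[, k], alpha = alpha))))
  if (adjust == "BH") {
    out$p_adjusted <- p.adjust(out$p_value, "BH")
    out$significant <- out$p_adjusted < alpha
  }
  out
}

#' Packaged chromosome size and position-category table
#'
#' Per-chromosome reference table shipped with the package: GRCh37
#' assembly length in Mb and the radial position category (peripheral /
#' intermediate / interior) in proliferating, quiescent and senescent
#' fibroblasts. Categories marked \code{"stated"} in the
#' \code{provenance} column are reported outcomes of the erosion assay
#' collated in the positioning literature for these cells; cells marked
#' \code{"inferred"} are completed from the reported lists of which
#' chromosomes do (and do not) change category between conditions,
#' choosing the placement consistent with all of those lists.
#'
#' @return Data frame with columns \code{chromosome}, \code{size_mb},
#'   \code{proliferating}, \code{quiescent}, \code{senescent},
#'   \code{provenance}.
#' @examples
#' head(chromosomePositions())
#' @export
chromosomePositions <- function() {
  path <- system.file("extdata", "chromosome_positions.csv",
                      package = "radialFISH", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Association between chromosome size and radial category
#'
#' Rank correlation (Kendall's tau-b, tie-corrected normal p-value)
#' between chromosome size in Mb and the ordinal position category coded
#' interior < intermediate < peripheral. A positive tau means larger
#' chromosomes sit closer to the nuclear periphery. In non-proliferating
#' (quiescent, senescent) fibroblasts territory positions adhere more to
#' chromosome size than in proliferating cells, so tau is expected to be
#' larger there.
#'
#' @param records data frame with a \code{size_mb} column and one
#'   category column per condition (as from [chromosomePositions()]).
#' @param condition name of the category column to test.
#' @return One-row data frame: \code{condition}, \code{n}, \code{tau},
#'   \code{p_value}.
#' @examples
#' sizeCategoryAssociation(chromosomePositions(), "senescent")
#' @export
sizeCategoryAssociation <- function(records, condition) {
  stopifnot(is.data.frame(records), "size_mb" %in% names(records),
            condition %in% names(records))
  if (nrow(records) < 5L) stop("at least 5 chromosome records are required")
  lev <- c("interior", "intermediate", "peripheral")
  cat <- records[[condition]]
  if (!all(cat %in% lev))
    stop("categories must be interior/intermediate/peripheral")
  if (length(unique(cat)) == 1L)
    stop("all records share one category; the correlation is undefined")
  size <- records$size_mb
  if (length(unique(size)) == 1L)
    return(data.frame(condition = condition, n = nrow(records), tau = 0,
                      p_value = 1))
  ord <- as.integer(factor(cat, levels = lev))
  ct <- suppressWarnings(cor.test(size, ord, method = "kendall",
                                  exact = FALSE))
  data.frame(condition = condition, n = nrow(records),
             tau = unname(ct$estimate), p_value = ct$p.value)
}
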