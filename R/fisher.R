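# Contingency table construction and the exact test contrasting pseudogene
# fractions between two lineage groups.

#' Build a 2x2 pseudogene-vs-intact contingency table by lineage group
#'
#' Counts sequence observations (species x locus), not distinct loci. Entries
#' whose status is neither "intact" nor "pseudogene" (e.g. "absent") are
#' excluded; the number excluded is recorded on the result.
#'
#' @param classifications data.frame with columns `species`, `locus`, `status`.
#' @param groups named character vector mapping every species to one of exactly
#'   two group labels.
#' @return an object of class `or_contingency`: a 2x2 integer matrix with rows
#'   = groups and columns = c("pseudogene", "intact"), with attribute
#'   `excluded` giving the number of dropped observations.
#' @export
contingency_table <- function(classifications, groups) {
  if (!is.data.frame(classifications) || nrow(classifications) == 0L)
    stop("no classifications supplied")
  stopifnot(all(c("species", "status") %in% names(classifications)))
  sp <- as.character(classifications$species)
  ungrouped <- setdiff(unique(sp), names(groups))
  if (length(ungrouped))
    stop("species without a group assignment: ", paste(ungrouped, collapse = ", "))
  lev <- unique(unname(groups))
  if (length(lev) != 2L)
    stop("groups must define exactly two group labels, got: ",
         paste(lev, collapse = ", "))
  keep <- classifications$status %in% c("pseudogene", "intact")
  excluded <- sum(!keep)
  cl <- classifications[keep, , drop = FALSE]
  if (nrow(cl) == 0L) stop("no intact/pseudogene observations to tabulate")
  g <- factor(unname(groups[as.character(cl$species)]), levels = lev)
  s <- factor(cl$status, levels = c("pseudogene", "intact"))
  tab <- table(g, s)
  m <- matrix(as.integer(tab), 2, 2, dimnames = list(lev, c("pseudogene", "intact")))
  structure(m, class = c("or_contingency", "matrix"), excluded = excluded)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration over all tables with the
#' observed margins, summing the probabilities of tables no more probable than
#' the observed one (the minimum-likelihood two-sided rule), with a relative
#' tolerance of 1e-12 on the "no more probable" comparison. Probabilities are
#' accumulated in log space.
#'
#' @param table an `or_contingency`, a 2x2 matrix, or a numeric vector
#'   c(a, b, c, d) read row-wise.
#' @return list with elements `p.value`, `table`, and `proportions` (row-wise
#'   pseudogene fractions when column names are available).
#' @export
fisher_exact <- function(table) {
  m <- if (is.matrix(table)) table else matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  n <- a + b + cc + d
  if (n == 0) stop("empty table")
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("degenerate table (zero margin); p = 1 by convention")
    p <- 1.0
  } else {
    x <- max(0, c1 - r2):min(r1, c1)
    logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
    lobs <- logp[x == a]
    keep <- logp <= lobs + log1p(1e-12)
    # log-sum-exp over the retained outcomes
    mx <- max(logp[keep])
    p <- min(1, exp(mx) * sum(exp(logp[keep] - mx)))
  }
  props <- m[, 1] / rowSums(m)
  list(p.value = p, table = m, proportions = props)
}
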