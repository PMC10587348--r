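# Order-parameter axis specification. Each residue is tagged with an axis:
# 1 for the first order parameter, 2 for the second (2D landscapes), 0 for
# residues tracked by neither (allowed but unusual). Bins are indexed by
# integer native counts; n = k/N only at the presentation layer.

#' Define the order parameter(s) of a landscape
#'
#' @param n Residue count.
#' @param region1 Residues contributing to the first order parameter
#'   (default: all residues; sets may be non-contiguous).
#' @param region2 Optional residues of a second order parameter; must be
#'   disjoint from `region1`.
#' @return Object of class `wsme_order_spec` with `axis` (length-n vector in
#'   {0,1,2}), `n1`, `n2`, and `two_d`.
#' @export
order_spec <- function(n, region1 = seq_len(n), region2 = NULL) {
  region1 <- as.integer(region1)
  stopifnot(all(region1 >= 1), all(region1 <= n), !anyDuplicated(region1))
  axis <- integer(n)
  axis[region1] <- 1L
  if (!is.null(region2)) {
    region2 <- as.integer(region2)
    stopifnot(all(region2 >= 1), all(region2 <= n), !anyDuplicated(region2))
    if (length(intersect(region1, region2)) > 0)
      stop("order-parameter regions must be disjoint")
    axis[region2] <- 2L
  }
  structure(list(n = n, axis = axis,
                 n1 = sum(axis == 1L), n2 = sum(axis == 2L),
                 two_d = any(axis == 2L)),
            class = "wsme_order_spec")
}

#' @export
print.wsme_order_spec <- function(x, ...) {
  cat("<wsme_order_spec> N=", x$n, if (x$two_d)
    paste0(" 2D (N1=", x$n1, ", N2=", x$n2, ")") else
      paste0(" 1D (N1=", x$n1, ")"), "\n", sep = "")
  invisible(x)
}

same_spec <- function(a, b) {
  a$n == b$n && identical(a$axis, b$axis)
}

new_partition_table <- function(lm, sg, spec, temperature) {
  structure(list(lm = lm, sg = sg, spec = spec, temperature = temperature),
            class = "wsme_partition_table")
}

#' @export
print.wsme_partition_table <- function(x, ...) {
  cat("<wsme_partition_table> bins ", nrow(x$lm), "x", ncol(x$lm),
      " T=", x$temperature, "K  log Z(total)=",
      format(logsumexp(x$lm[x$sg > 0])), "\n", sep = "")
  invisible(x)
}

#' Partition-table values on the plain (non-log) scale
#'
#' Convenience accessor; overflows to Inf for very stable systems, in which
#' case work with the `lm`/`sg` fields directly.
#' @param table A `wsme_partition_table`.
#' @return Numeric matrix (K1+1) x (K2+1) of signed values.
#' @export
partition_values <- function(table) {
  table$sg * exp(table$lm)
}

#' Total (unrestricted) log partition function
#' @param table A `wsme_partition_table` with all-positive bins.
#' @return log Z summed over all bins.
#' @export
log_partition_total <- function(table) {
  if (any(table$sg < 0)) stop("partition table has negative bins")
  logsumexp(table$lm[table$sg > 0])
}
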