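#' Gacs-Korner common random variable of the sources
#'
#' The finest random variable that is a deterministic function of every
#' source simultaneously. It is computed as the connected components of the
#' support graph: vertices are supported source symbols (across all sources)
#' and each support point `(x1, ..., xn)` connects the symbols that co-occur
#' in it. Any random variable expressible as `Q = f_i(X_i)` for every source
#' `i` is a coarsening of this component labeling.
#'
#' @param pmf a [joint_pmf()] with at least 2 sources.
#' @return an object of class `common_variable` with fields `labeling` (one
#'   integer vector per source mapping each alphabet index to a block id, `NA`
#'   for symbols off the support) and `n_blocks`.
#' @examples
#' gacs_korner_common(make_canonical("RDNXOR"))$n_blocks # 2
#' @export
gacs_korner_common <- function(pmf) {
  stopifnot(inherits(pmf, "joint_pmf"))
  n <- pmf$n_sources
  if (n < 2) {
    stop("common variable needs >= 2 sources; use mutual_information_bits for self-redundancy")
  }
  sizes <- vapply(pmf$source_alphabets, length, 1L)
  offset <- c(0L, cumsum(sizes))[seq_len(n)]
  n_nodes <- sum(sizes)

  parent <- seq_len(n_nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
    invisible(NULL)
  }

  sup <- pmf_support(pmf)
  pts <- sup$points
  for (r in seq_len(nrow(pts))) {
    a <- offset[1] + pts[r, 1]
    for (i in 2:n) union_(a, offset[i] + pts[r, i])
  }

  supported <- vector("list", n)
  for (i in seq_len(n)) supported[[i]] <- sort(unique(pts[, i]))

  roots <- unique(vapply(offset[1] + supported[[1]], find, 1L))
  block_of_root <- stats::setNames(seq_along(roots), roots)

  labeling <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- rep(NA_integer_, sizes[i])
    lab[supported[[i]]] <- block_of_root[as.character(
      vapply(offset[i] + supported[[i]], find, 1L)
    )]
    labeling[[i]] <- lab
  }
  structure(
    list(labeling = labeling, n_blocks = length(roots)),
    class = "common_variable"
  )
}

#' @export
print.common_variable <- function(x, ...) {
  cat(sprintf("common_variable: %d block(s) over %d source(s)\n",
              x$n_blocks, length(x$labeling)))
  invisible(x)
}

#' Exact redundancy via the Gacs-Korner common variable, in bits
#'
#' Returns `I(Y; C)` where `C` is the common random variable from
#' [gacs_korner_common()]. By the data-processing inequality this equals the
#' maximum of `I(Y; Q)` over all `Q` that are deterministic functions of
#' every source, i.e. the deterministic-common-variable notion of redundant
#' information.
#'
#' @param pmf a [joint_pmf()] with at least 2 sources.
#' @return redundancy in bits.
#' @examples
#' i_cap_wedge_bits(make_canonical("RDNXOR")) # 1
#' i_cap_wedge_bits(make_canonical("IMPERFECTRDN")) # 0
#' @export
i_cap_wedge_bits <- function(pmf) {
  cv <- gacs_korner_common(pmf)
  sup <- pmf_support(pmf)
  ny <- length(pmf$target_alphabet)
  joint <- matrix(0, nrow = cv$n_blocks, ncol = ny)
  lab1 <- cv$labeling[[1]]
  for (r in seq_len(nrow(sup$points))) {
    q <- lab1[sup$points[r, 1]]
    y <- sup$points[r, pmf$n_sources + 1]
    joint[q, y] <- joint[q, y] + sup$mass[r]
  }
  hq <- entropy_from_masses(rowSums(joint))
  hy <- entropy_from_masses(colSums(joint))
  hqy <- entropy_from_masses(as.vector(joint))
  max(hq + hy - hqy, 0)
}
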