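#' Construct a finite joint probability table over sources and a target
#'
#' A `joint_pmf` stores an explicit probability mass function over
#' `(X1, ..., Xn, Y)` with named finite alphabets. Alphabet symbols may be
#' scalars or tuples (vectors); tuples are the natural representation for
#' composite sources such as a pair of bits.
#'
#' @param source_alphabets list with one alphabet per source; each alphabet is
#'   either an atomic vector of scalar symbols or a list of symbol vectors
#'   (tuples).
#' @param target_alphabet alphabet of the target variable, same conventions.
#' @param table numeric array of probability masses with
#'   `dim = c(|X1|, ..., |Xn|, |Y|)`; must be non-negative and sum to 1
#'   within `1e-12`.
#' @return an object of class `joint_pmf` with fields `source_alphabets`,
#'   `target_alphabet`, `table`, `n_sources`.
#' @examples
#' # a fair coin copied into one source
#' pmf <- joint_pmf(list(c(0, 1)), c(0, 1), diag(2) / 2)
#' entropy_bits(pmf, "y")
#' @export
joint_pmf <- function(source_alphabets, target_alphabet, table) {
  stopifnot(is.list(source_alphabets), length(source_alphabets) >= 1)
  source_alphabets <- lapply(source_alphabets, as_alphabet)
  target_alphabet <- as_alphabet(target_alphabet)
  sizes <- c(vapply(source_alphabets, length, 1L), length(target_alphabet))
  table <- as.array(table)
  if (length(dim(table)) != length(sizes) || !all(dim(table) == sizes)) {
    stop("`table` must have dim c(", paste(sizes, collapse = ", "), ")")
  }
  if (any(table < 0)) stop("probability masses must be non-negative")
  s <- sum(table)
  if (abs(s - 1) > 1e-12) {
    stop(sprintf("probability masses must sum to 1 (got %.15f)", s))
  }
  if (all(table == 0)) stop("support must be non-empty")
  structure(
    list(
      source_alphabets = source_alphabets,
      target_alphabet = target_alphabet,
      table = table,
      n_sources = length(source_alphabets)
    ),
    class = "joint_pmf"
  )
}

# Normalize an alphabet to a list of symbol vectors.
as_alphabet <- function(x) {
  if (is.list(x)) {
    if (length(x) == 0) stop("alphabet must be non-empty")
    return(x)
  }
  if (length(x) == 0) stop("alphabet must be non-empty")
  as.list(x)
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat(sprintf(
    "joint_pmf: %d source(s) %s, target |Y| = %d, support size %d\n",
    x$n_sources,
    paste0("|X", seq_len(x$n_sources), "| = ",
           vapply(x$source_alphabets, length, 1L), collapse = ", "),
    length(x$target_alphabet),
    sum(x$table > 0)
  ))
  invisible(x)
}

# Variable names are "x1", ..., "xn" and "y".
pmf_var_dims <- function(pmf, which) {
  if (length(which) == 0) stop("variable subset must be non-empty")
  which <- unique(as.character(which))
  valid <- c(paste0("x", seq_len(pmf$n_sources)), "y")
  bad <- setdiff(which, valid)
  if (length(bad) > 0) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "))
  }
  vapply(which, function(v) {
    if (v == "y") pmf$n_sources + 1L else as.integer(sub("^x", "", v))
  }, 1L)
}

# Marginal mass function over a variable subset, as a (possibly
# multidimensional) array.
marginal_table <- function(pmf, which) {
  dims <- sort(pmf_var_dims(pmf, which))
  apply(pmf$table, dims, sum)
}

entropy_from_masses <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Plug-in Shannon entropy of a marginal, in bits
#'
#' @param pmf a [joint_pmf()].
#' @param which character vector of variable names among
#'   `"x1", ..., "xn", "y"`.
#' @return marginal entropy H(which) in bits (log base 2); `0 * log(0)` is
#'   treated as 0.
#' @examples
#' entropy_bits(make_canonical("AND"), "y") # 0.8113 bits
#' @export
entropy_bits <- function(pmf, which) {
  stopifnot(inherits(pmf, "joint_pmf"))
  entropy_from_masses(as.vector(marginal_table(pmf, which)))
}

#' Mutual information between two variable subsets, in bits
#'
#' `I(A; B) = H(A) + H(B) - H(A, B)`, computed by plug-in from the joint
#' table. The result is clipped to 0 from below at `1e-12` rounding scale.
#'
#' @param pmf a [joint_pmf()].
#' @param A,B disjoint non-empty character vectors of variable names.
#' @return I(A;B) in bits.
#' @examples
#' mutual_information_bits(make_canonical("AND"), "x1", "y") # 0.3113
#' @export
mutual_information_bits <- function(pmf, A, B) {
  stopifnot(inherits(pmf, "joint_pmf"))
  if (length(intersect(A, B)) > 0) stop("`A` and `B` must be disjoint")
  mi <- entropy_bits(pmf, A) + entropy_bits(pmf, B) - entropy_bits(pmf, c(A, B))
  max(mi, 0)
}

#' Conditional mutual information I(A; B | C), in bits
#'
#' Computed as `H(A,C) + H(B,C) - H(A,B,C) - H(C)`.
#'
#' @param pmf a [joint_pmf()].
#' @param A,B,C pairwise disjoint variable subsets (C non-empty).
#' @return I(A;B|C) in bits, clipped to 0 from below.
#' @export
conditional_mi_bits <- function(pmf, A, B, C) {
  stopifnot(inherits(pmf, "joint_pmf"))
  if (length(intersect(A, B)) > 0 || length(intersect(A, C)) > 0 ||
      length(intersect(B, C)) > 0) {
    stop("`A`, `B`, `C` must be pairwise disjoint")
  }
  cmi <- entropy_bits(pmf, c(A, C)) + entropy_bits(pmf, c(B, C)) -
    entropy_bits(pmf, c(A, B, C)) - entropy_bits(pmf, C)
  max(cmi, 0)
}

# Support of the pmf: matrix of alphabet indices (one row per support point,
# n_sources + 1 columns) plus the mass vector.
pmf_support <- function(pmf) {
  idx <- which(pmf$table > 0)
  pts <- arrayInd(idx, dim(pmf$table))
  list(points = pts, mass = pmf$table[idx])
}

symbol_label <- function(sym) paste(as.character(sym), collapse = ";")

#' Write a joint pmf to CSV
#'
#' Columns are `x1, ..., xn, y, p`; tuple symbols are joined with `";"`.
#' Zero-mass cells are omitted.
#'
#' @param pmf a [joint_pmf()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(pmf, path) {
  sup <- pmf_support(pmf)
  n <- pmf$n_sources
  cols <- lapply(seq_len(n), function(i) {
    vapply(sup$points[, i], function(k) symbol_label(pmf$source_alphabets[[i]][[k]]), "")
  })
  y <- vapply(sup$points[, n + 1], function(k) symbol_label(pmf$target_alphabet[[k]]), "")
  df <- as.data.frame(cols, col.names = paste0("x", seq_len(n)))
  df$y <- y
  df$p <- sup$mass
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

parse_symbol <- function(label) {
  parts <- strsplit(label, ";", fixed = TRUE)[[1]]
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) nums else parts
}

#' Read a joint pmf from CSV
#'
#' Inverse of [write_pmf_csv()]. Alphabets are recovered from the distinct
#' symbol strings in order of first appearance; numeric-looking symbols are
#' parsed back to numbers.
#'
#' @param path CSV file with columns `x1, ..., xn, y, p`.
#' @return a [joint_pmf()].
#' @export
read_pmf_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  if (!("p" %in% names(df)) || !("y" %in% names(df))) {
    stop("pmf CSV must have columns x1, ..., xn, y, p")
  }
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  if (length(xcols) == 0) stop("pmf CSV must have at least one source column")
  p <- as.numeric(df$p)
  alpha <- lapply(df[xcols], function(col) lapply(unique(col), parse_symbol))
  ylevels <- unique(df$y)
  target <- lapply(ylevels, parse_symbol)
  sizes <- c(vapply(alpha, length, 1L), length(target))
  tab <- array(0, dim = sizes)
  idx <- cbind(
    do.call(cbind, lapply(seq_along(xcols), function(i) {
      match(df[[xcols[i]]], unique(df[[xcols[i]]]))
    })),
    match(df$y, ylevels)
  )
  tab[idx] <- p
  joint_pmf(unname(alpha), target, tab)
}
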