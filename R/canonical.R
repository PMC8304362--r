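#' Canonical partial-information-decomposition benchmark distributions
#'
#' Builds the joint pmf of one of four standard two-source tasks used to
#' benchmark redundancy measures:
#'
#' * `UNQ`: `a, b` iid uniform bits; `X1 = a`, `X2 = b`, `Y = (a, b)`. Each
#'   source holds 1 bit of unique information, none redundant.
#' * `AND`: `X1, X2` iid uniform bits, `Y = X1 AND X2`. Redundancy lies in
#'   `[0, 0.311]` bits depending on the redundancy notion; deterministic
#'   common-variable redundancy is 0.
#' * `RDNXOR`: `a, b, c` iid uniform bits; `X1 = (a, c)`, `X2 = (b, c)`,
#'   `Y = (a XOR b, c)`. One bit redundant (the shared bit `c`) and one bit
#'   synergistic.
#' * `IMPERFECTRDN`: `P(x1=0, x2=0, y=0) = 0.499`, `P(0, 1, 0) = 0.001`,
#'   `P(1, 1, 1) = 0.5`. `X1` specifies `Y` exactly; `X2` misses it with
#'   probability 0.001, so `I(X2; Y) = 0.99` bits.
#'
#' @param task one of `"UNQ"`, `"AND"`, `"RDNXOR"`, `"IMPERFECTRDN"`
#'   (case-insensitive).
#' @return a [joint_pmf()].
#' @examples
#' mutual_information_bits(make_canonical("IMPERFECTRDN"), "x2", "y")
#' @export
make_canonical <- function(task) {
  task <- toupper(as.character(task)[1])
  bits2 <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  pair_idx <- function(u, v) 2L * u + v + 1L
  switch(
    task,
    UNQ = {
      tab <- array(0, dim = c(2, 2, 4))
      for (a in 0:1) for (b in 0:1) {
        tab[a + 1, b + 1, pair_idx(a, b)] <- 0.25
      }
      joint_pmf(list(c(0, 1), c(0, 1)), bits2, tab)
    },
    AND = {
      tab <- array(0, dim = c(2, 2, 2))
      for (a in 0:1) for (b in 0:1) {
        tab[a + 1, b + 1, (a & b) + 1] <- 0.25
      }
      joint_pmf(list(c(0, 1), c(0, 1)), c(0, 1), tab)
    },
    RDNXOR = {
      tab <- array(0, dim = c(4, 4, 4))
      for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
        tab[pair_idx(a, cc), pair_idx(b, cc), pair_idx(xor(a, b) * 1, cc)] <- 1 / 8
      }
      joint_pmf(list(bits2, bits2), bits2, tab)
    },
    IMPERFECTRDN = {
      tab <- array(0, dim = c(2, 2, 2))
      tab[1, 1, 1] <- 0.499
      tab[1, 2, 1] <- 0.001
      tab[2, 2, 2] <- 0.5
      joint_pmf(list(c(0, 1), c(0, 1)), c(0, 1), tab)
    },
    stop("unknown canonical task: ", task,
         " (expected UNQ, AND, RDNXOR or IMPERFECTRDN)")
  )
}

canonical_task_names <- function() c("UNQ", "AND", "RDNXOR", "IMPERFECTRDN")
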