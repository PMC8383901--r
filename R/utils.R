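#' @importFrom stats optimize rpois runif rexp rbinom quantile prcomp sd
#'   setNames
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Complement of DNA bases
#' @param x character vector of single bases (A/C/G/T)
#' @return complemented bases
#' @keywords internal
complementBase <- function(x) {
  out <- unname(.complement[x])
  if (anyNA(out) && !anyNA(x)) stop("invalid base(s): ",
                                    paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Is a substitution a transversion?
#'
#' A transversion exchanges a purine for a pyrimidine (or vice versa); the
#' unordered transition pairs are \{A,G\} and \{C,T\}.
#'
#' @param anc,der character vectors of single bases
#' @return logical vector
#' @export
isTransversion <- function(anc, der) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  pa <- purine[anc]
  pd <- purine[der]
  if (anyNA(pa) || anyNA(pd)) stop("invalid base(s) in anc/der")
  unname(pa != pd)
}

#' Transversion-only mutation rate implied by a total rate
#'
#' With a genome-wide average mutation rate and a transition:transversion
#' ratio, the rate attributable to transversions alone is
#' `total / (1 + tsTv)`. With the human defaults (1.25e-8 per bp per
#' generation, Ts:Tv = 2) this gives ~4.17e-9, i.e. 4e-9 to one significant
#' figure, the rate appropriate for branch-length work restricted to
#' transversions.
#'
#' @param totalRate total per-bp per-generation mutation rate
#' @param tsTv transition:transversion ratio
#' @return transversion-only rate, same units as `totalRate`
#' @export
transversionRate <- function(totalRate = 1.25e-8, tsTv = 2) {
  stopifnot(totalRate > 0, tsTv >= 0)
  totalRate / (1 + tsTv)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded helpers do not
#' perturb the global stream. A `NULL` seed uses the current stream.
#'
#' @param seed integer seed or NULL
#' @param expr expression to evaluate
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Overlap of [l, r] with [a, b], elementwise; returns lengths >= 0.
.overlap <- function(l, r, a, b) pmax(0, pmin(r, b) - pmax(l, a))
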