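# Evaluate an expression under a temporary RNG state.
# Keeps the caller's RNG untouched so seeded helpers compose predictably.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12289L) %% 2147483647)
}

#' Jaccard coefficient of two sets
#'
#' `|A intersect B| / |A union B|`; the edge weight of the phenoclustering
#' graph and the overlap score of the bootstrap stability analysis.
#'
#' @param a,b vectors treated as sets.
#' @return scalar in `[0, 1]` (0 when both sets are empty).
#' @export
jaccard_coefficient <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Format a two-sided p-value honestly near the double floor.
format_pvalue <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", formatC(p, format = "g", digits = 4))
}
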