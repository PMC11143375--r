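#' @importFrom stats p.adjust pchisq pnorm phyper dhyper rbinom rpois rnbinom
#'   rlnorm rnorm runif rbeta rgeom plogis qlogis glm.fit binomial setNames
#'   wilcox.test var aggregate model.matrix logLik anova glm predict cor.test
#'   complete.cases lowess approx optimize uniroot sd quantile
#' @importFrom utils head modifyList write.table read.table
#' @importFrom methods as is
#' @import data.table
NULL

# Derive a child seed from a run seed and a stage tag so that independent
# generators never share an RNG stream. Kept below 2^31-1.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, tag).
with_seed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, tag))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bh_fdr <- function(p) p.adjust(p, method = "BH")

stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
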