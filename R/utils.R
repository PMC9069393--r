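# Seed handling: every generator draws from its own seeded stream and
# restores the caller's RNG state, so generators are pure functions of
# (spec, seed) with no hidden global state.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# lognormal multiplicative noise with mean 1 and coefficient of
# variation cv
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Write ground truth metadata to YAML
#'
#' Every synthetic dataset is serialised alongside the full record of its
#' generating parameters so downstream expectations can be computed
#' without re-deriving the generator.
#'
#' @param truth a `ground_truth` list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  yaml::write_yaml(.yaml_safe(truth), path)
  invisible(path)
}

#' Read ground truth metadata
#' @param path YAML path.
#' @return the ground-truth list.
#' @export
read_ground_truth <- function(path) {
  structure(yaml::read_yaml(path), class = "ground_truth")
}

.yaml_safe <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), .yaml_safe))
  if (is.function(x)) return("<function>")
  if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
  x
}
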