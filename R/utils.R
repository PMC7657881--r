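# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# column-name-safe version of a design-code label ("familiarity:talk" -> "familiarity_x_talk")
sanitize_label <- function(x) gsub(":", "_x_", x, fixed = TRUE)

# md5 of an in-memory object via its canonical JSON serialization
object_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
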