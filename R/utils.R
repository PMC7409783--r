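#' @keywords internal
"_PACKAGE"

# Condition constructors -------------------------------------------------
#
# Every user-facing failure is a classed condition so callers (and the CLI,
# which maps classes to exit codes) can react programmatically:
#   refstab_schema_error / refstab_parse_error / refstab_integrity_error /
#   refstab_contract_error / refstab_config_error -> bad input (exit 2)
#   refstab_insufficient_data / refstab_domain_error -> not enough / invalid
#   data for the requested statistic (exit 3)

rs_abort <- function(msg, class, data = list()) {
  stop(structure(
    class = c(class, "refstab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  ))
}

rs_schema_error       <- function(msg, ...) rs_abort(msg, "refstab_schema_error", list(...))
rs_parse_error        <- function(msg, ...) rs_abort(msg, "refstab_parse_error", list(...))
rs_integrity_error    <- function(msg, ...) rs_abort(msg, "refstab_integrity_error", list(...))
rs_contract_error     <- function(msg, ...) rs_abort(msg, "refstab_contract_error", list(...))
rs_config_error       <- function(msg, ...) rs_abort(msg, "refstab_config_error", list(...))
rs_domain_error       <- function(msg, ...) rs_abort(msg, "refstab_domain_error", list(...))
rs_insufficient_data  <- function(msg, ...) rs_abort(msg, "refstab_insufficient_data", list(...))

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values before averaging.
#' @return The geometric mean, `exp(mean(log(x)))`.
#' @examples
#' geo_mean(c(1, 0.25))  # 0.5
#' @export
geo_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0, na.rm = TRUE)) {
    rs_domain_error("geometric mean requires strictly positive values")
  }
  exp(mean(log(x)))
}

# Run `expr` under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic competition-free ranking: ties broken by `tiebreak` (a second
# numeric key) and then by position in `names`.
rank_deterministic <- function(values, tiebreak = NULL, names = seq_along(values)) {
  if (is.null(tiebreak)) tiebreak <- seq_along(values)
  ord <- order(values, tiebreak, names)
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
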