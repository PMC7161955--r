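`%||%` <- function(x, y) if (is.null(x)) y else x

.clip01 <- function(x) pmin(1, pmax(0, x))

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' One master seed deterministically yields one sub-seed per named stage, so a
#' whole pipeline run is reproducible from a single integer. The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed master seed (single integer).
#' @param stage character stage name.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((abs(seed) + 10007 * h) %% 2147483646 + 1)
}

.package_version_string <- function() {
  as.character(utils::packageVersion("iesret"))
}

# md5 of the YAML rendering of any list-like object; used to stamp output
# files so a run is identifiable from its configuration alone.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}

.meta_header <- function(meta = NULL) {
  lines <- sprintf("# iesret %s", .package_version_string())
  if (!is.null(meta)) {
    for (nm in names(meta))
      lines <- c(lines, sprintf("# %s: %s", nm,
                                paste(format(meta[[nm]]), collapse = " ")))
  }
  lines
}
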