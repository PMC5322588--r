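DNA_BASES <- c("A", "C", "G", "T")

# IUPAC codes other than the four unambiguous bases
IUPAC_AMBIGUOUS <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

VALID_ALPHABET <- c(DNA_BASES, IUPAC_AMBIGUOUS)

#' Derive a reproducible substream seed from a master seed and a key
#'
#' Combines an integer master seed with a character key (for example a genus
#' name or a defect-channel name) into a new seed, so that independent
#' substreams can be drawn without one stream perturbing another. The hash is
#' a plain 31-bit polynomial rolling hash: stable across platforms and R
#' sessions.
#'
#' @param seed Integer master seed.
#' @param key Character scalar naming the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "genus:Agaricus")
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key),
            length(key) == 1)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer((h + (abs(seed) %% m) * 48271) %% m)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Uppercase, normalize U to T, and check the IUPAC alphabet.
canonicalize_sequence <- function(x, context = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  if (any(!nzchar(x)))
    stop(context, " must be non-empty", call. = FALSE)
  bad <- grepl(paste0("[^", paste(VALID_ALPHABET, collapse = ""), "]"), x)
  if (any(bad))
    stop(context, " contains characters outside the IUPAC nucleotide alphabet",
         call. = FALSE)
  x
}

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("`", name, "` must be a probability in [0, 1]", call. = FALSE)
  p
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x))
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  as.integer(x)
}
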