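# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Canonical internal index names from user-facing spellings.
INDEX_NAMES <- c(mi = "mi", cn = "cn", ra = "ra",
                 "lnb-cn" = "lnb_cn", lnb_cn = "lnb_cn",
                 "lnb-ra" = "lnb_ra", lnb_ra = "lnb_ra",
                 car = "car", cra = "cra", random = "random")

match_index <- function(index) {
  key <- tolower(as.character(index)[1L])
  if (!key %in% names(INDEX_NAMES)) {
    stop("unknown index '", index, "'; use one of MI, CN, RA, LNB-CN, ",
         "LNB-RA, CAR, CRA (or 'random' for the chance baseline)",
         call. = FALSE)
  }
  unname(INDEX_NAMES[key])
}

# Order-free string key for an unordered labelled pair; labels never contain
# whitespace (the edge-list grammar forbids it), so tab is a safe separator.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}
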