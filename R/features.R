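#' One-hot atom-type features
#'
#' @param s a \code{qa_structure}.
#' @param table atom-type table, see [atom_type_table()].
#' @return n_atoms x 11 0/1 matrix, each row one-hot over the atom-type
#'   categories.
#' @export
encode_atoms <- function(s, table = atom_type_table()) {
  types <- assign_atom_types(s, table)
  m <- matrix(0, nrow(s$atoms), 11L)
  m[cbind(seq_along(types), types + 1L)] <- 1
  colnames(m) <- atom_type_names()
  m
}

#' Residue embedding providers
#'
#' Residue-level input features come from a pluggable provider, a pure
#' function of the amino-acid sequence:
#' \describe{
#'   \item{onehot}{20-dimensional indicator of residue identity.}
#'   \item{random}{a fixed-seed Gaussian lookup table by residue
#'     identity with a chosen dimension; useful as a cheap stand-in
#'     embedding in tests.}
#'   \item{plm}{an adapter for an external protein language model whose
#'     per-residue output is 1024-dimensional; the caller supplies the
#'     embedding function (\code{fun}), since the model weights are an
#'     optional external dependency.}
#' }
#'
#' @param name one of \code{"onehot"}, \code{"random"}, \code{"plm"}.
#' @param dim output dimension (fixed: onehot 20, plm 1024; free for
#'   random).
#' @param seed seed for the random provider's lookup table.
#' @param fun for the plm provider: \code{function(sequence)} returning
#'   an n x 1024 matrix.
#' @param variant model variant name recorded in cache headers.
#' @return list of class \code{qa_embedding_provider}.
#' @export
embedding_provider <- function(name = c("onehot", "random", "plm"),
                               dim = NULL, seed = 1L, fun = NULL,
                               variant = NULL) {
  name <- match.arg(name)
  dim <- switch(name,
                onehot = 20L,
                random = as.integer(if (is.null(dim)) 32L else dim),
                plm = 1024L)
  if (name == "plm" && !is.null(fun)) {
    stopifnot(is.function(fun))
  }
  structure(list(name = name, dim = dim, seed = as.integer(seed),
                 fun = fun, variant = variant, deterministic = TRUE),
            class = "qa_embedding_provider")
}

#' Per-residue embedding matrix for a sequence
#'
#' @param sequence one-letter amino-acid string (standard 20 letters).
#' @param provider an [embedding_provider()].
#' @return n_residues x dim numeric matrix.
#' @export
embed_residues <- function(sequence, provider = embedding_provider("onehot")) {
  stopifnot(inherits(provider, "qa_embedding_provider"),
            is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  letters1 <- strsplit(sequence, "")[[1]]
  pos <- match(letters1, .qa_aa1)
  if (anyNA(pos)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(letters1[is.na(pos)]), collapse = ", "))
  }
  n <- length(pos)
  switch(provider$name,
    onehot = {
      m <- matrix(0, n, 20L)
      m[cbind(seq_len(n), pos)] <- 1
      colnames(m) <- .qa_aa1
      m
    },
    random = {
      # fixed-seed Gaussian table: one row per residue identity
      rng <- .qa_local_rng(provider$seed)
      tab <- matrix(rng$rnorm(20L * provider$dim), 20L, provider$dim)
      tab[pos, , drop = FALSE]
    },
    plm = {
      if (is.null(provider$fun)) {
        stop("plm provider not configured: supply `fun` with the model's ",
             "per-residue embedding function (1024-dim output)")
      }
      m <- provider$fun(sequence)
      if (!is.matrix(m) || nrow(m) != n || ncol(m) != 1024L) {
        stop("plm embedding function must return an n x 1024 matrix")
      }
      m
    })
}

# scoped RNG: draws numbers from a private stream without touching
# the global .Random.seed
.qa_local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  use <- function(expr_fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
    })
    expr_fun(...)
  }
  list(rnorm = function(...) use(stats::rnorm, ...),
       runif = function(...) use(stats::runif, ...),
       sample = function(...) use(base::sample, ...),
       sample_int = function(...) use(base::sample.int, ...))
}

#' Write or read a cached embedding matrix
#'
#' Cache files are plain text: a one-line header
#' \code{provider <name> dim <d> variant <v>} followed by one
#' whitespace-separated row per residue.  Files are keyed by the
#' sequence so all decoys of a target share one entry.
#'
#' @param sequence one-letter amino-acid string.
#' @param provider an [embedding_provider()].
#' @param cache_dir directory for cache files.
#' @return the embedding matrix (computed and cached, or read back).
#' @export
embed_residues_cached <- function(sequence, provider, cache_dir) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- .qa_hash(paste(provider$name, provider$dim, sequence, sep = "|"))
  path <- file.path(cache_dir, paste0(key, ".emb"))
  if (file.exists(path)) {
    hdr <- readLines(path, n = 1L)
    m <- as.matrix(read.table(path, skip = 1L))
    dimnames(m) <- NULL
    return(m)
  }
  m <- embed_residues(sequence, provider)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("provider %s dim %d variant %s", provider$name,
                     provider$dim, provider$variant %||% "none"), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic string hash (djb2 over utf8 bytes, hex)
.qa_hash <- function(x) {
  b <- utf8ToInt(x)
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", as.integer(h))
}
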