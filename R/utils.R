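# Shared helpers: residue alphabet, label sanitation, seeds, config hashing,
# and headered TSV input/output used by every stage.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
ALPHABET <- c(AA20, "X")

#' Normalize protein residues
#'
#' Uppercases a residue string and maps ambiguity/rare codes (B, Z, U, J, O)
#' to X, which is treated as missing data downstream. Any character outside
#' the 20-letter alphabet plus X after this mapping is an error.
#'
#' @param x character vector of residue strings.
#' @return character vector over the 21-letter alphabet.
#' @export
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- chartr("BZUJO", "XXXXX", x)
  bad <- grepl(paste0("[^", paste(ALPHABET, collapse = ""), "]"), x)
  if (any(bad)) {
    ch <- setdiff(unique(strsplit(paste(x[bad], collapse = ""), "")[[1]]), ALPHABET)
    stop("non-amino-acid characters after normalization: ",
         paste(ch, collapse = " "))
  }
  x
}

encode_residues <- function(x) {
  # 1-based integer encoding over ALPHABET
  m <- match(strsplit(x, "")[[1]], ALPHABET)
  if (anyNA(m)) stop("unencodable residues in sequence")
  m
}

#' Sanitize genome labels for Newick safety
#'
#' Spaces and Newick-reserved punctuation become underscores. Returns the
#' sanitized labels; the mapping old -> new is attached as the "label_map"
#' attribute so it can be written alongside results.
#'
#' @param x character vector of labels.
#' @export
sanitize_labels <- function(x) {
  y <- gsub("[][ \t():;,']", "_", x)
  y <- gsub("_+", "_", y)
  if (anyDuplicated(y)) stop("labels collide after sanitization: ",
                             paste(y[duplicated(y)], collapse = ", "))
  attr(y, "label_map") <- data.frame(original = x, sanitized = y,
                                     stringsAsFactors = FALSE)
  y
}

# djb2-style rolling hash over the deparsed config, mod a Mersenne prime;
# a stable, dependency-free fingerprint for output headers and the run
# manifest (not cryptographic).
config_hash <- function(x) {
  if (is.list(x) && !is.null(names(x))) x <- x[order(names(x))]
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Per-stage RNG streams derived from one run seed; keeps every stage
# reproducible independently of execution order. Result < 2^31.
stage_seed <- function(seed, stage, k = 0L) {
  sv <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + sv * 31 + k) %% 2147483629)
}

#' Write a TSV with a provenance header
#'
#' Every tabular output starts with a comment line recording the config hash
#' and run seed, so results are attributable to one configuration.
#' @param df data.frame.
#' @param path output path.
#' @param config run configuration list (needs `$seed`), or NULL.
#' @export
write_tsv_headered <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    cat(sprintf("# hgtscan config=%s seed=%s\n", config_hash(config),
                as.character(config$seed %||% "NA")), file = con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_headered()]
#' @param path input path.
#' @export
read_tsv_headered <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) {
  message("[hgtscan] ", sprintf(...))
}
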