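# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

ZONES <- c("synonymous", "nonsynonymous", "noncoding")
CATEGORY_LEVELS <- c(as.character(1:7), "total")
BASES <- c("A", "C", "G", "T")

stop_synsig <- function(msg, ..., class = "synsig_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Chromosome names are normalized by stripping a leading "chr" so that
# MAF/WIG/GTF/FASTA dialect drift across consortia cannot split one
# chromosome into two keys.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

is_single_base <- function(x) x %in% BASES

complement_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- map[toupper(x)]
  out[is.na(out)] <- "N"
  unname(out)
}

# md5 of a canonical serialization, used for provenance headers.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

# fwrite with provenance comment header (fread skips comment lines on read).
write_tsv_provenance <- function(dt, path, provenance = NULL) {
  hdr <- c(
    sprintf("# synsig %s", as.character(utils::packageVersion("synsig"))),
    if (!is.null(provenance)) sprintf("# %s", provenance)
  )
  writeLines(hdr, path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

# as.data.table without copying when the input is already a data.table
# (as.data.table() deep-copies tables carrying extra classes)
as_dt <- function(x) {
  if (data.table::is.data.table(x)) x else as.data.table(x)
}

read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

# Evaluate code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
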