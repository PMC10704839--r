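# Mutation category assignment.
#
# Seven categories by triplet context and substitution type:
#   1 transition at a CpG dinucleotide          2 transversion at CpG
#   3 transition at C:G not in CpG              4 transversion at C:G not in CpG
#   5 transition at A:T                         6 transversion at A:T
#   7 indels and null-type events
# Categories 1-6 are defined on base-pair identity, so they are invariant
# under strand complementation; CpG status is read on the reference forward
# strand (a C followed by G, or a G preceded by C).

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Assign a mutation category from ref/alt and triplet context
#'
#' @param ref reference allele; a single base, or `"-"`/multi-base for indels.
#' @param alt alternate allele, same conventions.
#' @param context reference-strand triplet centred on the mutated base
#'   (ignored for indels; `"N"` flanks are treated as non-CpG).
#' @return integer vector of categories in 1..7.
#' @examples
#' categorize_mutation("C", "T", "ACG") # CpG transition -> 1
#' categorize_mutation("A", "G", "TAT") # A:T transition -> 5
#' @export
categorize_mutation <- function(ref, alt, context = "NNN") {
  n <- max(length(ref), length(alt), length(context))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  context <- toupper(rep_len(as.character(context), n))

  snv <- is_single_base(ref) & is_single_base(alt)
  if (any(snv & ref == alt)) {
    stop_synsig("invalid mutation record: ref equals alt")
  }

  out <- rep.int(7L, n)
  if (!any(snv)) return(out)

  r <- ref[snv]
  a <- alt[snv]
  ctx <- context[snv]
  prev <- substr(ctx, 1L, 1L)
  nxt <- substr(ctx, 3L, 3L)

  ts <- TRANSITIONS[r] == a
  cg <- r %in% c("C", "G")
  cpg <- (r == "C" & nxt == "G") | (r == "G" & prev == "C")

  cat6 <- ifelse(cg & cpg, ifelse(ts, 1L, 2L),
          ifelse(cg,       ifelse(ts, 3L, 4L),
                           ifelse(ts, 5L, 6L)))
  out[snv] <- cat6
  out
}

# Lookup: is changing codon position `pos` to base `alt` synonymous?
# 64 x 3 x 4 logical array built once from the standard genetic code.
build_synonymy_lookup <- function() {
  codons <- apply(expand.grid(BASES, BASES, BASES,
                              stringsAsFactors = FALSE)[, 3:1], 1, paste0,
                  collapse = "")
  gc <- Biostrings::GENETIC_CODE
  arr <- array(NA, dim = c(64L, 3L, 4L),
               dimnames = list(codons, NULL, BASES))
  for (ci in seq_along(codons)) {
    cod <- codons[ci]
    aa <- gc[[cod]]
    for (p in 1:3) {
      for (b in BASES) {
        mut <- cod
        substr(mut, p, p) <- b
        arr[ci, p, b] <- identical(gc[[mut]], aa)
      }
    }
  }
  arr
}

.synsig_env <- new.env(parent = emptyenv())

synonymy_lookup <- function() {
  if (is.null(.synsig_env$syn_lookup)) {
    .synsig_env$syn_lookup <- build_synonymy_lookup()
  }
  .synsig_env$syn_lookup
}
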