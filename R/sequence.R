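# Sequence handling for prion-like domains: residue taxonomy, composition
# statistics, variant-label parsing, and composition-preserving mutagenesis.

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Six-way residue taxonomy used throughout: aromatics and charged residues
# act as "stickers", the remainder as "spacers". Asn/Gln carry pi electrons
# but no net charge ("neutral_pi"); glycine is its own class.
RESIDUE_CLASSES <- list(
  aromatic   = c("F", "W", "Y"),
  positive   = c("K", "H", "R"),
  negative   = c("D", "E"),
  neutral_pi = c("N", "Q"),
  glycine    = "G",
  neutral    = c("A", "C", "I", "L", "M", "P", "S", "T", "V")
)

# Replacement pool for composition-biased "deletion" variants: the weakly
# interacting residues used to stand in for removed stickers. Fixed order
# also serves as the tie-break order in largest-remainder rounding.
WEAK_RESIDUES <- c("S", "T", "G", "A")

#' Construct a prion-like-domain sequence object
#'
#' @param id character label.
#' @param residues character vector of one-letter amino-acid codes, or a
#'   single string that is split into characters.
#' @return An object of class `pld_sequence` with fields `id`, `residues`
#'   and length `L`.
#' @export
pld_sequence <- function(id, residues) {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(residues)
  bad <- which(!residues %in% AA_CANONICAL)
  if (length(bad) > 0L) {
    stop(sprintf("sequence '%s': non-canonical residue '%s' at position %d",
                 id, residues[bad[1]], bad[1]), call. = FALSE)
  }
  if (length(residues) < 1L) {
    stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  }
  structure(list(id = as.character(id), residues = residues,
                 L = length(residues)),
            class = "pld_sequence")
}

#' @export
print.pld_sequence <- function(x, ...) {
  cat(sprintf("<pld_sequence> %s (L = %d)\n", x$id, x$L))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' @export
format.pld_sequence <- function(x, ...) paste(x$residues, collapse = "")

#' Read protein sequences from a FASTA file
#'
#' Each record becomes a [pld_sequence()]; lowercase input is uppercased and
#' any non-canonical residue is rejected with the record and position named.
#'
#' @param path path to a FASTA file.
#' @return A list of `pld_sequence` objects, record order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  out <- vector("list", length(aas))
  ids <- sub("\\s.*$", "", names(aas))
  for (i in seq_along(aas)) {
    out[[i]] <- pld_sequence(ids[i], as.character(aas[[i]]))
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a `pld_sequence` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "pld_sequence")) seqs <- list(seqs)
  ss <- Biostrings::AAStringSet(vapply(seqs, format.pld_sequence, ""))
  names(ss) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Classify a residue into the six-class taxonomy
#'
#' @param aa one-letter amino-acid code (vectorised).
#' @return character vector of class names among aromatic, positive,
#'   negative, neutral_pi, glycine, neutral.
#' @export
classify_residue <- function(aa) {
  aa <- toupper(aa)
  bad <- setdiff(unique(aa), AA_CANONICAL)
  if (length(bad) > 0L) {
    stop("non-canonical residue code: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map <- character(0)
  for (cl in names(RESIDUE_CLASSES)) map[RESIDUE_CLASSES[[cl]]] <- cl
  unname(map[aa])
}

#' Formal-charge model for residues
#'
#' Default assigns +1 to Arg and Lys, -1 to Asp and Glu, 0 elsewhere.
#' Histidine is compositionally grouped with the positives but carries no
#' formal charge by default; set `his_charge` to override (e.g. for low-pH
#' scenarios).
#'
#' @param his_charge formal charge on histidine (elementary charges).
#' @return named numeric vector over the 20 canonical residues.
#' @export
charge_model <- function(his_charge = 0) {
  q <- stats::setNames(numeric(20), AA_CANONICAL)
  q[c("R", "K")] <- 1
  q[c("D", "E")] <- -1
  q["H"] <- his_charge
  q
}

#' Composition profile and net charge per residue
#'
#' @param seq a [pld_sequence()].
#' @param charges a charge model as from [charge_model()].
#' @return list with `fractions` (named over the six classes, summing to 1),
#'   `counts`, and `ncpr` (net charge per residue, dimensionless).
#' @export
composition_profile <- function(seq, charges = charge_model()) {
  stopifnot(inherits(seq, "pld_sequence"))
  cls <- classify_residue(seq$residues)
  counts <- stats::setNames(integer(length(RESIDUE_CLASSES)),
                            names(RESIDUE_CLASSES))
  tab <- table(factor(cls, levels = names(RESIDUE_CLASSES)))
  counts[names(tab)] <- as.integer(tab)
  ncpr <- sum(charges[seq$residues]) / seq$L
  list(fractions = counts / seq$L, counts = counts, ncpr = ncpr)
}

# ---- Mutation specifications ------------------------------------------------

#' Construct a mutation specification
#'
#' A mutation spec describes a single substitution type: `n` residues drawn
#' from `source` replaced by `target`. Target `"X"` denotes
#' composition-biased replacement by weakly interacting residues.
#'
#' @param source character vector of source residue codes (e.g. `"R"`, or
#'   `c("F","Y")` for an F/Y family).
#' @param target single residue code or `"X"`.
#' @param n number of substitutions.
#' @param positions optional 1-based positions (length `n`).
#' @param multi_type logical; set by [infer_mutation()] when substitutions
#'   span more than one source-target pair.
#' @return object of class `mutation_spec`.
#' @export
mutation_spec <- function(source, target, n, positions = NULL,
                          multi_type = FALSE) {
  source <- toupper(source)
  target <- toupper(target)
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative", call. = FALSE)
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != n) {
      stop("positions length must equal n", call. = FALSE)
    }
  }
  if (target != "X" && target %in% source) {
    stop("source and target residues must be disjoint", call. = FALSE)
  }
  structure(list(source = source, target = target, n = n,
                 positions = positions, multi_type = isTRUE(multi_type)),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("<mutation_spec> %s (n = %d%s)\n", pair_label(x), x$n,
              if (x$multi_type) ", multi-type" else ""))
  invisible(x)
}

#' Mutation-pair label, e.g. "Y->F" or "F/Y->X"
#' @param spec a [mutation_spec()].
#' @return single string.
#' @export
pair_label <- function(spec) {
  paste0(paste(spec$source, collapse = "/"), "->", spec$target)
}

#' Mutation fraction f = N / L for a spec bound to a sequence length
#' @param spec a [mutation_spec()].
#' @param L protein length.
#' @return numeric fraction.
#' @export
mutation_fraction <- function(spec, L) spec$n / L

#' Parse a variant label of the form "-nX+mZ" or "-nX"
#'
#' The convention: `-nX+nZ` replaces n residues of type X with n residues of
#' type Z; `-nX` alone replaces n residues of X with weakly interacting
#' residues in proportion to the sequence's compositional bias (target
#' `"X"`). Both the Unicode minus (U+2212) and the ASCII hyphen are
#' accepted. A `-nX+mZ` label with n != m is rejected.
#'
#' @param label character label.
#' @return a [mutation_spec()].
#' @export
parse_variant_label <- function(label) {
  lab <- gsub("−", "-", trimws(label))
  m <- regmatches(lab, regexec(
    "^-([0-9]+)([A-Za-z/]+)(\\+([0-9]+)([A-Za-z]+))?$", lab))[[1]]
  if (length(m) == 0L || m[1] != lab) {
    stop("unparseable variant label: '", label, "'", call. = FALSE)
  }
  n <- as.integer(m[2])
  src <- toupper(strsplit(m[3], "/")[[1]])
  if (m[4] == "") {
    return(mutation_spec(src, "X", n))
  }
  m2 <- as.integer(m[5])
  tgt <- toupper(m[6])
  if (n != m2) {
    stop("variant label '", label, "' removes ", n, " but adds ", m2,
         " residues; counts must match", call. = FALSE)
  }
  mutation_spec(src, tgt, n)
}

#' Format a mutation spec as a variant label
#' @param spec a [mutation_spec()].
#' @return string such as `"-12F+12Y"` or `"-10Y"`.
#' @export
format_variant_label <- function(spec) {
  src <- paste(spec$source, collapse = "/")
  if (spec$target == "X") {
    sprintf("-%d%s", spec$n, src)
  } else {
    sprintf("-%d%s+%d%s", spec$n, src, spec$n, spec$target)
  }
}

#' Infer the substitution set between a wild type and a variant
#'
#' Sequences must be equal length (this dataset substitutes, never inserts
#' or deletes). If the substitutions span more than one source-target
#' residue pair the result is flagged `multi_type`; downstream scaling fits
#' refuse flagged specs.
#'
#' @param wt,variant [pld_sequence()] objects of equal length.
#' @return a [mutation_spec()] with `positions` set.
#' @export
infer_mutation <- function(wt, variant) {
  stopifnot(inherits(wt, "pld_sequence"), inherits(variant, "pld_sequence"))
  if (wt$L != variant$L) {
    stop("sequences differ in length (", wt$L, " vs ", variant$L,
         "); only substitutions are supported", call. = FALSE)
  }
  pos <- which(wt$residues != variant$residues)
  if (length(pos) == 0L) {
    return(mutation_spec(character(0), "X", 0L, integer(0)))
  }
  pairs <- unique(paste(wt$residues[pos], variant$residues[pos]))
  src <- sort(unique(wt$residues[pos]))
  tgt <- unique(variant$residues[pos])
  multi <- length(pairs) > 1L
  mutation_spec(src,
                if (length(tgt) == 1L) tgt else "X",
                length(pos), pos, multi_type = multi)
}

# Evenly spaced selection: indices round(j*(M-1)/(N-1)), j = 0..N-1, into
# the ordered occurrence list; a single mutation takes the middle occurrence.
evenly_spaced_indices <- function(M, N) {
  if (N == 0L) return(integer(0))
  if (N == 1L) return(as.integer(ceiling(M / 2)))
  1L + as.integer(round((seq_len(N) - 1L) * (M - 1) / (N - 1)))
}

# Largest-remainder apportionment of n replacements across the weak-residue
# pool, proportional to wild-type counts; ties broken in fixed order
# S < T < G < A, then by seed.
largest_remainder <- function(counts, n, seed) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop("wild type has no weakly interacting residues to draw from",
         call. = FALSE)
  }
  quota <- n * counts / sum(counts)
  base <- floor(quota)
  rem <- quota - base
  short <- n - sum(base)
  if (short > 0) {
    ord_fixed <- match(names(counts), WEAK_RESIDUES)
    ord_fixed[is.na(ord_fixed)] <- length(WEAK_RESIDUES) + seq_len(
      sum(is.na(ord_fixed)))
    set.seed(seed)
    jitter <- stats::runif(length(counts))
    ord <- order(-rem, ord_fixed, jitter)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  rep(names(counts), times = base)
}

#' Design a sequence variant under the dataset's construction rules
#'
#' Applies a [mutation_spec()] to a wild-type sequence following the rules
#' used to build the variant family: exactly `n` source residues are
#' replaced; replaced positions are spread homogeneously along the chain
#' (evenly spaced quantiles of the source-residue occurrence list); and for
#' target `"X"` the replacement letters are weakly interacting residues
#' (Ser, Thr, Gly, Ala) in proportion to their wild-type counts, so the
#' compositional bias of the spacer background is preserved.
#'
#' @param wt wild-type [pld_sequence()].
#' @param spec a [mutation_spec()].
#' @param seed integer seed controlling tie-breaks and the assignment of
#'   replacement letters to positions.
#' @return a new `pld_sequence` named `<wt id>_<label>`.
#' @export
design_variant <- function(wt, spec, seed = 1L) {
  stopifnot(inherits(wt, "pld_sequence"), inherits(spec, "mutation_spec"))
  if (spec$n == 0L) return(wt)
  occ <- which(wt$residues %in% spec$source)
  if (length(occ) < spec$n) {
    stop(sprintf(
      "cannot mutate %d of %s: wild type has only %d (short by %d)",
      spec$n, paste(spec$source, collapse = "/"), length(occ),
      spec$n - length(occ)), call. = FALSE)
  }
  pos <- if (!is.null(spec$positions)) {
    spec$positions
  } else {
    occ[evenly_spaced_indices(length(occ), spec$n)]
  }
  res <- wt$residues
  if (spec$target == "X") {
    weak_counts <- table(factor(wt$residues[wt$residues %in% WEAK_RESIDUES],
                                levels = WEAK_RESIDUES))
    repl <- largest_remainder(
      stats::setNames(as.integer(weak_counts), WEAK_RESIDUES), spec$n, seed)
    set.seed(seed)
    repl <- sample(repl)
  } else {
    repl <- rep(spec$target, spec$n)
  }
  res[pos] <- repl
  pld_sequence(paste0(wt$id, "_", format_variant_label(spec)), res)
}

#' Summarise variants against a wild type as a table
#'
#' @param wt wild-type [pld_sequence()].
#' @param variants list of `pld_sequence` objects.
#' @return data.frame with columns variant_id, wt_id, label, L, N, fraction,
#'   multi_type.
#' @export
variant_table <- function(wt, variants) {
  rows <- lapply(variants, function(v) {
    sp <- infer_mutation(wt, v)
    data.frame(variant_id = v$id, wt_id = wt$id,
               label = format_variant_label(sp),
               L = wt$L, N = sp$n, fraction = sp$n / wt$L,
               multi_type = sp$multi_type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
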