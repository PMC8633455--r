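## Secondary-structure folding and duplex hybridisation.
##
## The energy model is a deliberately small nearest-neighbour one:
## stacking energies for adjacent base pairs (AU/GC/GU classes), additive
## loop penalties (hairpin, bulge, interior, affine multibranch), a
## 3-nt minimum hairpin loop and a 30-nt interior-loop cap. Energies are
## handled internally as integers in decikcal/mol so that minimisation is
## exact and platform-independent. Absolute values are not meant to match
## a full Turner parameter set; every threshold used downstream is either
## a ratio internal to this model or re-examined on synthetic data.

.mirwood_env <- new.env(parent = emptyenv())

PAIR_NAMES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Energy parameters for the folding model
#'
#' Reads the packaged stacking-energy and loop-penalty tables and expands
#' them into integer (decikcal/mol) lookup vectors. Loop penalties beyond
#' the tabulated sizes are extrapolated as `E(L) = E(L0) + 1.078 * log(L/L0)`
#' kcal/mol (a Jacobson-Stockmayer style log term), rounded to 0.1 kcal/mol.
#'
#' @param max_len maximum loop size to tabulate (>= longest sequence folded).
#' @param stack_file,loop_file optional TSV overrides with the same layout
#'   as the packaged `stack_energies.tsv` / `loop_penalties.tsv`.
#' @return a list with integer components `stack` (6x6 matrix over pair
#'   types AU, UA, GC, CG, GU, UG), `hairpin`, `bulge`, `internal` (indexed
#'   by loop size), multibranch coefficients `ml_a`, `ml_b`, `ml_c`, and the
#'   model constants `max_interior` and `min_hairpin`.
#' @export
energy_parameters <- function(max_len = 600L, stack_file = NULL,
                              loop_file = NULL) {
  key <- paste0("par_", max_len, "_", is.null(stack_file), is.null(loop_file))
  if (is.null(stack_file) && is.null(loop_file) &&
      !is.null(.mirwood_env[[key]])) {
    return(.mirwood_env[[key]])
  }
  if (is.null(stack_file)) {
    stack_file <- system.file("extdata", "stack_energies.tsv",
                              package = "mirwood")
  }
  if (is.null(loop_file)) {
    loop_file <- system.file("extdata", "loop_penalties.tsv",
                             package = "mirwood")
  }
  st <- utils::read.delim(stack_file, check.names = FALSE)
  stopifnot(identical(st$pair, PAIR_NAMES))
  stack <- as.matrix(st[, PAIR_NAMES])
  rownames(stack) <- PAIR_NAMES
  stack_int <- matrix(as.integer(round(stack * 10)), 6, 6,
                      dimnames = dimnames(stack))

  lp <- utils::read.delim(loop_file)
  get1 <- function(type) lp$energy[lp$type == type][1]
  coef_dk <- get1("extrapolation_coef") * 10
  expand <- function(type) {
    rows <- lp[lp$type == type, ]
    sizes <- rows$size
    base <- as.integer(round(rows$energy * 10))
    out <- rep(NA_integer_, max_len)
    out[sizes] <- base
    L0 <- max(sizes)
    if (max_len > L0) {
      L <- (L0 + 1):max_len
      out[L] <- base[sizes == L0] + as.integer(round(coef_dk * log(L / L0)))
    }
    out[is.na(out)] <- .Machine$integer.max %/% 4L
    out
  }
  par <- list(
    stack = stack_int,
    hairpin = expand("hairpin"),
    bulge = expand("bulge"),
    internal = expand("internal"),
    ml_a = as.integer(round(get1("multiloop_closing") * 10)),
    ml_b = as.integer(round(get1("multiloop_branch") * 10)),
    ml_c = as.integer(round(get1("multiloop_unpaired") * 10)),
    max_interior = as.integer(get1("max_interior")),
    min_hairpin = as.integer(get1("min_hairpin"))
  )
  if (grepl("TRUETRUE", key)) .mirwood_env[[key]] <- par
  par
}

## sequence utilities ------------------------------------------------------

#' Reverse complement of a DNA or RNA string
#' @param x character vector of sequences.
#' @param out `"DNA"` or `"RNA"` output alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x, out = c("DNA", "RNA")) {
  out <- match.arg(out)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  if (out == "RNA") rc <- chartr("T", "U", rc)
  unname(rc)
}

as_rna <- function(x) chartr("T", "U", toupper(x))

as_dna <- function(x) chartr("U", "T", toupper(x))

#' @keywords internal
rna_codes <- function(seq) {
  seq <- toupper(seq)
  if (grepl("T", seq, fixed = TRUE)) {
    message("T bases transcribed to U")
    seq <- chartr("T", "U", seq)
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- match(v, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) {
    stop("invalid characters in sequence: ",
         paste(unique(v[is.na(codes)]), collapse = ", "))
  }
  codes
}

## folding -----------------------------------------------------------------

#' Fold a single RNA sequence into its minimum-free-energy structure
#'
#' Zuker-style dynamic programme over the packaged energy model. The empty
#' structure has energy zero, so the reported MFE is always <= 0. Ties are
#' broken by a fixed deterministic traceback order (pairing preferred over
#' leaving a base unpaired, leftmost pair first; stacking/interior before
#' multibranch before hairpin closure).
#'
#' @param seq RNA string (`A/C/G/U`; `T` is transcribed to `U` with a
#'   message), 10-500 nt.
#' @param par energy parameters from [energy_parameters()].
#' @return an object of class `fold_result`: list with `seq`, `structure`
#'   (dot-bracket), `mfe` (kcal/mol) and `energy_dk` (integer decikcal).
#' @examples
#' rna_fold("GGGGAAAACCCC")$structure
#' @export
rna_fold <- function(seq, par = energy_parameters()) {
  stopifnot(length(seq) == 1L)
  codes <- rna_codes(seq)
  n <- length(codes)
  if (n < 10L || n > 500L) stop("sequence length must be in [10, 500]")
  res <- fold_dp(codes, par$stack, par$hairpin, par$bulge, par$internal,
                 par$ml_a, par$ml_b, par$ml_c, par$max_interior,
                 par$min_hairpin)
  structure(list(seq = chartr("T", "U", toupper(seq)),
                 structure = res$structure,
                 mfe = res$energy / 10,
                 energy_dk = res$energy),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, " (", sprintf("%.1f", x$mfe), ")\n", sep = "")
  invisible(x)
}

#' Write fold results in Vienna dot-bracket format
#' @param folds a `fold_result` or list of them; `file` output path.
#' @param ids sequence names.
#' @export
write_dotbracket <- function(folds, file, ids = NULL) {
  if (inherits(folds, "fold_result")) folds <- list(folds)
  if (is.null(ids)) ids <- paste0("seq", seq_along(folds))
  lines <- unlist(lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    c(paste0(">", ids[i]), f$seq,
      paste0(f$structure, " (", sprintf("%.1f", f$mfe), ")"))
  }))
  writeLines(lines, file)
  invisible(file)
}

#' Base-pair table of a dot-bracket string
#' @param db dot-bracket string.
#' @return two-column integer matrix of paired positions (1-based, i < j).
#' @export
db_pairs <- function(db) {
  v <- strsplit(db, "", fixed = TRUE)[[1]]
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  pairs <- list()
  for (p in seq_along(v)) {
    if (v[p] == "(") {
      open <- c(open, p)
    } else if (v[p] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      pairs[[length(pairs) + 1L]] <- c(open[length(open)], p)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  if (length(pairs)) out <- do.call(rbind, pairs)
  colnames(out) <- c("i", "j")
  out[order(out[, 1]), , drop = FALSE]
}

#' Hybridisation energy of two RNA strands
#'
#' Optimal antiparallel intermolecular pairing (no intramolecular pairs, no
#' pseudoknots) under the same stacking/loop model as [rna_fold()]. There is
#' no initiation term: a duplex with no favourable pairing has energy 0.
#'
#' @param a,b RNA strings (T accepted), each 1-40 nt.
#' @param par energy parameters.
#' @return object of class `duplex_result`: `strand_a`, `strand_b`,
#'   `pairing` (matrix of 1-based index pairs, a-index vs b-index), `mfe`
#'   (kcal/mol).
#' @export
duplex_mfe <- function(a, b, par = energy_parameters()) {
  ca <- rna_codes(a)
  cb <- rna_codes(b)
  if (length(ca) < 1L || length(ca) > 40L || length(cb) < 1L ||
      length(cb) > 40L) {
    stop("duplex strands must be 1-40 nt")
  }
  res <- duplex_dp(ca, cb, par$stack, par$bulge, par$internal,
                   par$max_interior)
  structure(list(strand_a = chartr("T", "U", toupper(a)),
                 strand_b = chartr("T", "U", toupper(b)),
                 pairing = cbind(i = res$i, j = res$j),
                 mfe = res$energy / 10,
                 energy_dk = res$energy),
            class = "duplex_result")
}

#' Test whether a fold is a single stem-loop carrying a tag on one arm
#'
#' A qualifying precursor folds into exactly one hairpin (a single terminal
#' loop, no multibranch loops) and the candidate small RNA must sit on one
#' arm of the stem without crossing the terminal loop onto the other arm.
#' A tag may overhang into the loop region (Dicer leaves 2-nt 3' overhangs)
#' as long as it does not reach the opposite arm.
#'
#' @param fold a `fold_result`.
#' @param tag the small RNA sequence (DNA or RNA); must occur in `fold$seq`.
#' @return list with `ok` (logical) and `arm` (`"5p"`, `"3p"` or `"none"`).
#' @export
is_stemloop <- function(fold, tag) {
  stopifnot(inherits(fold, "fold_result"))
  tag_rna <- chartr("T", "U", toupper(tag))
  pos <- regexpr(tag_rna, fold$seq, fixed = TRUE)[1]
  if (pos < 0) stop("tag not found in precursor sequence")
  t1 <- pos
  t2 <- pos + nchar(tag_rna) - 1L
  pr <- db_pairs(fold$structure)
  if (nrow(pr) == 0) return(list(ok = FALSE, arm = "none"))
  ## innermost pairs = hairpin loops; exactly one means a single stem-loop
  inner <- vapply(seq_len(nrow(pr)), function(k) {
    !any(pr[, 1] > pr[k, 1] & pr[, 2] < pr[k, 2])
  }, logical(1))
  if (sum(inner) != 1L) return(list(ok = FALSE, arm = "none"))
  lp <- pr[inner, ]
  on5 <- t1 <= lp[1]
  on3 <- t2 >= lp[2]
  if (on5 && on3) return(list(ok = FALSE, arm = "none"))
  if (on5) return(list(ok = TRUE, arm = "5p"))
  if (on3) return(list(ok = TRUE, arm = "3p"))
  list(ok = FALSE, arm = "none")
}
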