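# Model and sequence I/O: FASTA reading/writing with digitization, the
# HMMER3/f ASCII profile subset, the package's own TSV profile dialect,
# and quantization of real-valued log-odds to 8-bit unsigned / 16-bit
# signed saturating integer schemes.

#' Canonical amino-acid alphabet
#'
#' The 20 standard residues in the fixed order used for all emission
#' matrices and digitized codes 0..19. Ambiguity/non-standard codes
#' (B, J, O, U, X, Z) digitize to code 20.
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

AMBIG_CODES <- c("B","J","O","U","X","Z")

# Background residue frequencies of the standard protein null model
# (Swissprot 50.8 composition, as used by hmmsearch-style tools), in
# AA_ALPHABET20 order. Used to convert stored probabilities to log-odds.
AA_BACKGROUND <- c(
  0.0787945, 0.0151600, 0.0535222, 0.0668298, 0.0397062,
  0.0695071, 0.0229198, 0.0590092, 0.0594422, 0.0963728,
  0.0237718, 0.0414386, 0.0482904, 0.0395639, 0.0540978,
  0.0683364, 0.0540687, 0.0673417, 0.0114135, 0.0304133)

TRANS_NAMES <- c("MM","MI","MD","IM","II","DM","DD")

## ---------------------------------------------------------------------
## Digitized sequences

#' Digitize a protein sequence string
#'
#' Residues are mapped case-insensitively to integer codes 0..19 in
#' [AA_ALPHABET20] order; the ambiguity/non-standard codes B, J, O, U,
#' X, Z map to code 20. Any other character is an error.
#'
#' @param id Sequence identifier.
#' @param seq Character scalar of residues.
#' @return An object of class `digitized_seq` with fields `id`,
#'   `residues` (integer codes) and `length`.
#' @export
digitize_sequence <- function(id, seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- match(chars, AA_ALPHABET20) - 1L
  amb <- is.na(codes) & chars %in% AMBIG_CODES
  codes[amb] <- 20L
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf("illegal residue '%s' at position %d of record '%s'",
                 chars[bad], bad, id), call. = FALSE)
  }
  structure(list(id = as.character(id), residues = codes,
                 length = length(codes)),
            class = "digitized_seq")
}

#' @export
print.digitized_seq <- function(x, ...) {
  cat(sprintf("<digitized_seq '%s', %d residues>\n", x$id, x$length))
  invisible(x)
}

#' Read a protein FASTA file into digitized sequences
#'
#' @param path Path to a (possibly line-wrapped, multi-record) FASTA file.
#' @return List of [digitize_sequence()] objects, one per record.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) return(list())
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("malformed FASTA '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    digitize_sequence(ids[i], as.character(set[[i]])))
}

#' Write digitized sequences to a FASTA file
#'
#' Code 20 is written as `X`; the round trip through [read_fasta()]
#' reproduces ids and residue codes exactly.
#'
#' @param seqs List of `digitized_seq` objects.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  letters21 <- c(AA_ALPHABET20, "X")
  txt <- vapply(seqs, function(s)
    paste0(letters21[s$residues + 1L], collapse = ""), character(1))
  set <- Biostrings::BStringSet(txt)
  names(set) <- vapply(seqs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## ---------------------------------------------------------------------
## Profile models

#' Construct a profile HMM model
#'
#' A light container for a query profile: per-state match emission
#' log-odds (bits), optional insert emissions and core transitions
#' (needed by the Viterbi filter only), and the special-state
#' parameters of the multi-segment model.
#'
#' @param name Model name.
#' @param match_emissions `L x 20` numeric matrix of log-odds in bits
#'   (may contain `-Inf`), columns in [AA_ALPHABET20] order.
#' @param insert_emissions Optional `L x 20` matrix (bits). The filters
#'   score inserts at 0; these are carried for file round-trips.
#' @param transitions Optional `L x 7` matrix (bits, i.e. log2
#'   probabilities) with columns `MM, MI, MD, IM, II, DM, DD`; row `k`
#'   holds the transitions out of node `k` (`MM` is M_k -> M_(k+1), row
#'   `L` holds the exit M_L -> E in `MM`).
#' @param special_params Named list; any of `tloop`, `tmove`, `tbm`,
#'   `tec` (bits, all <= 0). `NULL` entries fall back to the
#'   length-dependent defaults described in [filter_constants()].
#' @return Object of class `profile_hmm`.
#' @export
profile_model <- function(name, match_emissions, insert_emissions = NULL,
                          transitions = NULL,
                          special_params = list()) {
  match_emissions <- as.matrix(match_emissions)
  L <- nrow(match_emissions)
  stopifnot(L >= 1, ncol(match_emissions) == 20)
  if (any(is.nan(match_emissions)) || any(match_emissions == Inf))
    stop("match emissions must be finite or -Inf", call. = FALSE)
  if (!is.null(transitions)) {
    transitions <- as.matrix(transitions)
    stopifnot(nrow(transitions) == L, ncol(transitions) == 7)
    colnames(transitions) <- TRANS_NAMES
    if (any(transitions > 0 & is.finite(transitions)))
      stop("transition log-odds must be <= 0 (log2 probabilities)",
           call. = FALSE)
  }
  if (!is.null(insert_emissions)) {
    insert_emissions <- as.matrix(insert_emissions)
    stopifnot(nrow(insert_emissions) == L, ncol(insert_emissions) == 20)
  }
  sp <- list(tloop = NULL, tmove = NULL, tbm = NULL, tec = -1)
  sp[names(special_params)] <- special_params
  structure(list(name = as.character(name), L = L,
                 match_emissions = unname(match_emissions),
                 insert_emissions = if (is.null(insert_emissions)) NULL
                                    else unname(insert_emissions),
                 transitions = transitions,
                 special_params = sp),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm '%s', L = %d%s>\n", x$name, x$L,
              if (is.null(x$transitions)) ", emissions only"
              else ", full core model"))
  invisible(x)
}

#' Read a profile from file
#'
#' Dispatches on the first line: `HMMER3/f` ASCII profiles (that dialect
#' only; other versions are rejected) or the package's TSV score-matrix
#' dialect written by [write_profile()].
#'
#' @param path Path to profile file.
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("empty profile file", call. = FALSE)
  if (startsWith(first, "HMMER3/f")) return(read_hmmer3(path))
  if (startsWith(first, "# hmmstripe-profile-tsv")) return(read_profile_tsv(path))
  if (startsWith(first, "HMMER"))
    stop(sprintf("unsupported profile format version: '%s' (only HMMER3/f is supported)",
                 first), call. = FALSE)
  stop("unrecognized profile format", call. = FALSE)
}

# HMMER3/f ASCII subset: NAME/LENG/ALPH headers, HMM symbol block, then
# per-node match-emission, insert-emission and transition lines. Stored
# values are -ln(probability) ('*' = zero probability); match scores are
# converted to log-odds bits against AA_BACKGROUND.
read_hmmer3 <- function(path) {
  lines <- readLines(path)
  nline <- function(i) if (i > length(lines))
    stop(sprintf("truncated HMMER3/f file at line %d", i), call. = FALSE)
    else lines[i]
  toks <- function(s) strsplit(trimws(s), "[ \t]+")[[1]]
  name <- NA_character_; L <- NA_integer_; alph <- NA_character_
  i <- 2
  while (i <= length(lines) && !startsWith(trimws(lines[i]), "HMM")) {
    tk <- toks(lines[i])
    if (length(tk) >= 2) {
      if (tk[1] == "NAME") name <- tk[2]
      if (tk[1] == "LENG") L <- as.integer(tk[2])
      if (tk[1] == "ALPH") alph <- tolower(tk[2])
    }
    i <- i + 1
  }
  if (i > length(lines)) stop("no HMM line found", call. = FALSE)
  if (is.na(L)) stop("missing LENG header", call. = FALSE)
  if (!identical(alph, "amino"))
    stop("only ALPH amino profiles are supported", call. = FALSE)
  sym <- toks(lines[i])[-1]
  if (!identical(sym[seq_len(20)], AA_ALPHABET20))
    stop(sprintf("unexpected symbol order at line %d", i), call. = FALSE)
  i <- i + 2                      # skip the m->m ... d->d header line
  # node 0: optional COMPO line, then insert-0 and transition-0 lines
  if (toks(nline(i))[1] == "COMPO") i <- i + 1
  i <- i + 2
  neglog <- function(x, line) {
    v <- suppressWarnings(as.numeric(ifelse(x == "*", Inf, x)))
    if (anyNA(v)) stop(sprintf("bad score field at line %d", line), call. = FALSE)
    v
  }
  me <- matrix(NA_real_, L, 20); ie <- matrix(NA_real_, L, 20)
  tr <- matrix(NA_real_, L, 7, dimnames = list(NULL, TRANS_NAMES))
  for (k in seq_len(L)) {
    tk <- toks(nline(i))
    if (tk[1] != as.character(k))
      stop(sprintf("expected node %d at line %d, found '%s'", k, i, tk[1]),
           call. = FALSE)
    if (length(tk) < 21) stop(sprintf("truncated node block at line %d", i),
                              call. = FALSE)
    me[k, ] <- neglog(tk[2:21], i)
    ie[k, ] <- neglog(toks(nline(i + 1))[1:20], i + 1)
    tr[k, ] <- neglog(toks(nline(i + 2))[1:7], i + 2)
    i <- i + 3
  }
  if (trimws(nline(i)) != "//")
    stop(sprintf("L mismatch: LENG %d but node blocks continue at line %d",
                 L, i), call. = FALSE)
  lnbg <- log(AA_BACKGROUND)
  bits_match  <- t((-t(me) - lnbg) / log(2))   # log2(p / bg)
  bits_insert <- t((-t(ie) - lnbg) / log(2))
  bits_trans  <- -tr / log(2)                  # log2(p)
  profile_model(name = if (is.na(name)) basename(path) else name,
                match_emissions = bits_match,
                insert_emissions = bits_insert,
                transitions = bits_trans)
}

#' Write a profile in HMMER3/f ASCII format
#'
#' Emissions are converted from log-odds bits back to stored
#' -ln(probability) values against the standard background; `-Inf`
#' log-odds are written as `*`. Reading the file back with
#' [read_profile()] reproduces the scores within text precision.
#'
#' @param model A `profile_hmm` with transitions and insert emissions.
#' @param path Output path.
#' @export
write_hmmer3_profile <- function(model, path) {
  stopifnot(inherits(model, "profile_hmm"), !is.null(model$transitions))
  ie <- model$insert_emissions
  if (is.null(ie)) ie <- matrix(0, model$L, 20)
  fmt <- function(x) ifelse(is.infinite(x), "      *",
                            sprintf("%8.5f", x))
  lnbg <- log(AA_BACKGROUND)
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("HMMER3/f [hmmstripe writer]")
  wl("NAME  ", model$name)
  wl("LENG  ", model$L)
  wl("ALPH  amino")
  wl("HMM     ", paste(sprintf("%8s", AA_ALPHABET20), collapse = " "))
  wl("        ", paste(sprintf("%8s",
        c("m->m","m->i","m->d","i->m","i->i","d->m","d->d")), collapse = " "))
  # node 0: flat insert-emission distribution; generic entry transitions
  # (skipped on read -- uniform-entry filter semantics do not use them)
  wl("        ", paste(fmt(rep(log(20), 20)), collapse = " "))
  wl("        ", paste(fmt(c(0.01, 4.6, 4.6, 0.6, 0.77, 0, Inf)), collapse = " "))
  for (k in seq_len(model$L)) {
    m_nl <- -(model$match_emissions[k, ] * log(2) + lnbg)
    i_nl <- -(ie[k, ] * log(2) + lnbg)
    t_nl <- -(model$transitions[k, ] * log(2))
    wl(sprintf("%7d ", k), paste(fmt(m_nl), collapse = " "),
       sprintf(" %7d - - -", k))
    wl("        ", paste(fmt(i_nl), collapse = " "))
    wl("        ", paste(fmt(t_nl), collapse = " "))
  }
  wl("//")
  invisible(path)
}

#' Write a profile in the package TSV dialect
#'
#' Layout (tab-separated, `-Inf` spelled `-inf`): a `# hmmstripe-profile-tsv v1`
#' header line; `name` and `length` records; then per node `k` a
#' `match k <20 bits>` line, optionally `insert k <20 bits>` and
#' `trans k <MM MI MD IM II DM DD>` lines; optionally
#' `special <tloop> <tmove> <tbm> <tec>` (with `.` for unset entries).
#'
#' @param model A `profile_hmm`.
#' @param path Output path.
#' @export
write_profile <- function(model, path) {
  stopifnot(inherits(model, "profile_hmm"))
  num <- function(x) ifelse(is.infinite(x), "-inf", sprintf("%.6f", x))
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(paste(..., sep = "\t"), con)
  writeLines("# hmmstripe-profile-tsv v1", con)
  wl("name", model$name)
  wl("length", model$L)
  sp <- model$special_params
  wl("special", paste(vapply(sp[c("tloop","tmove","tbm","tec")],
        function(v) if (is.null(v)) "." else num(v), character(1)),
        collapse = "\t"))
  for (k in seq_len(model$L)) {
    wl("match", k, paste(num(model$match_emissions[k, ]), collapse = "\t"))
    if (!is.null(model$insert_emissions))
      wl("insert", k, paste(num(model$insert_emissions[k, ]), collapse = "\t"))
    if (!is.null(model$transitions))
      wl("trans", k, paste(num(model$transitions[k, ]), collapse = "\t"))
  }
  invisible(path)
}

read_profile_tsv <- function(path) {
  lines <- readLines(path)
  stopifnot(startsWith(lines[1], "# hmmstripe-profile-tsv"))
  name <- "profile"; L <- NA_integer_
  me <- NULL; ie <- NULL; tr <- NULL
  sp <- list()
  pnum <- function(x, line) {
    v <- suppressWarnings(as.numeric(ifelse(x == "-inf", -Inf, x)))
    if (anyNA(v)) stop(sprintf("bad numeric field at line %d", line),
                       call. = FALSE)
    v
  }
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(trimws(lines[i]))) next
    tk <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    kind <- tk[1]
    if (kind == "name") { name <- tk[2]; next }
    if (kind == "length") {
      L <- as.integer(tk[2])
      me <- matrix(NA_real_, L, 20); ie <- matrix(NA_real_, L, 20)
      tr <- matrix(NA_real_, L, 7, dimnames = list(NULL, TRANS_NAMES))
      next
    }
    if (kind == "special") {
      v <- tk[-1]
      nm <- c("tloop","tmove","tbm","tec")
      sp <- setNames(lapply(seq_along(nm), function(j)
        if (v[j] == ".") NULL else pnum(v[j], i)), nm)
      next
    }
    if (kind %in% c("match","insert","trans")) {
      if (is.na(L)) stop("length record must precede score records",
                         call. = FALSE)
      k <- as.integer(tk[2])
      if (is.na(k) || k < 1 || k > L)
        stop(sprintf("state index out of range at line %d", i), call. = FALSE)
      vals <- pnum(tk[-(1:2)], i)
      if (kind == "match")  { stopifnot(length(vals) == 20); me[k, ] <- vals }
      if (kind == "insert") { stopifnot(length(vals) == 20); ie[k, ] <- vals }
      if (kind == "trans")  { stopifnot(length(vals) == 7);  tr[k, ] <- vals }
      next
    }
    stop(sprintf("unknown record type '%s' at line %d", kind, i),
         call. = FALSE)
  }
  if (is.na(L)) stop("missing length record", call. = FALSE)
  if (anyNA(me)) stop("L mismatch: missing match lines for some states",
                      call. = FALSE)
  profile_model(name, me,
                insert_emissions = if (anyNA(ie)) NULL else ie,
                transitions = if (anyNA(tr)) NULL else tr,
                special_params = sp)
}

## ---------------------------------------------------------------------
## Quantization

#' Default quantization scale and bias
#'
#' 8-bit unsigned scheme: scale of 3/ln(2) integer units per bit
#' (third-bits of a natural-log unit) and a bias that maps the minimum
#' finite emission to at least 1, keeping 0 free as the -Inf sentinel.
#' 16-bit signed scheme: 16 units per bit and bias 0.
#'
#' @param model A `profile_hmm`.
#' @param width `"8u"` or `"16s"`.
#' @return List with `scale` and `bias`.
#' @export
default_quantization <- function(model, width = c("8u", "16s")) {
  width <- match.arg(width)
  if (width == "16s") return(list(scale = 16, bias = 0L))
  scale <- 3 / log(2)
  fin <- model$match_emissions[is.finite(model$match_emissions)]
  lo <- if (length(fin)) round(scale * min(fin)) else 0
  list(scale = scale, bias = as.integer(max(0, 1 - lo)))
}

#' Quantize a profile's emission scores to saturating-integer units
#'
#' Each finite log-odds score `s` (bits) maps to
#' `clamp(round(scale * s) + bias, lo, hi)` in the target width; `-Inf`
#' maps to the sentinel (0 for 8u, -32768 for 16s; finite 16s values
#' are clamped to -32767 so the sentinel stays unambiguous). A 21st
#' column for the ambiguity code holds, per state, the worst finite
#' emission (conservative), or the sentinel if the state has none.
#'
#' @param model A `profile_hmm`.
#' @param width `"8u"` (MSV/SSV) or `"16s"` (Viterbi).
#' @param scale Positive units-per-bit factor; default per
#'   [default_quantization()].
#' @param bias Integer offset added after scaling.
#' @return Object of class `quantized_scores` with fields `width`,
#'   `scale`, `bias`, `sentinel`, `L` and `values` (`L x 21` integer
#'   matrix).
#' @export
quantize <- function(model, width = c("8u", "16s"), scale = NULL, bias = NULL) {
  width <- match.arg(width)
  def <- default_quantization(model, width)
  if (is.null(scale)) scale <- def$scale
  if (is.null(bias))  bias  <- def$bias
  stopifnot(scale > 0)
  em <- model$match_emissions
  amb <- apply(em, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) min(f) else -Inf
  })
  em21 <- unname(cbind(em, amb))
  q <- quantize_matrix(em21, width, scale, bias)
  structure(list(width = width, scale = scale, bias = as.integer(bias),
                 sentinel = if (width == "8u") 0L else -32768L,
                 L = model$L, values = q),
            class = "quantized_scores")
}

# Scalar/matrix quantizer shared by emissions and transitions.
quantize_matrix <- function(x, width, scale, bias) {
  if (width == "8u") { lo <- 0L; hi <- 255L; sent <- 0L }
  else               { lo <- -32767L; hi <- 32767L; sent <- -32768L }
  q <- round(scale * x) + bias
  q <- pmin(pmax(q, lo), hi)
  q[!is.finite(x)] <- sent
  mode(q) <- "integer"
  if (is.matrix(x)) q <- matrix(q, nrow(x), ncol(x), dimnames = dimnames(x))
  q
}

#' @export
print.quantized_scores <- function(x, ...) {
  cat(sprintf("<quantized_scores %s, L = %d, scale = %.4g, bias = %d>\n",
              x$width, x$L, x$scale, x$bias))
  invisible(x)
}

#' De-quantize integer scores back to bits
#'
#' Inverse of [quantize()] up to rounding: finite values map to
#' `(v - bias) / scale`; sentinels map to `-Inf`. For every finite
#' input score inside the representable range the round trip differs
#' from the original by at most `0.5 / scale`.
#'
#' @param qs A `quantized_scores`.
#' @return Numeric matrix of bits with `-Inf` at sentinel positions.
#' @export
dequantize <- function(qs) {
  v <- (qs$values - qs$bias) / qs$scale
  v[qs$values == qs$sentinel] <- -Inf
  v
}
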