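#' Default run configuration
#'
#' Flat named list of all pipeline parameters with documented defaults;
#' round-trips through \code{\link{writeRunConfig}} /
#' \code{\link{readRunConfig}}.
#'
#' @param ... Overrides of the defaults.
#' @return Named list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    model = "mechanistic",     # or "empirical"
    omega = 0.2,               # nonsynonymous/synonymous rate ratio
    kappa = 4.0,               # transition/transversion rate ratio
    theta = 0.5,               # nucleotide substitutions per codon
    piFile = "",               # codon frequency table ("" = uniform)
    empiricalFile = "",        # empirical codon matrix (model = empirical)
    singleGapPenalty = -12,    # frameshift gap
    tripleGapPenalty = -5,     # codon skip
    maxFrameshifts = 3,
    cutWidth = 128,            # cut-point spacing for the low-memory mode
    memoryMode = "full",       # or "cutpoint"
    calibrationFile = "",      # Gumbel calibration ("" = no E-values)
    orientation = "both",      # "forward", "reverse" or "both"
    seed = 1,
    verbose = FALSE)
  ov <- list(...)
  for (k in names(ov)) {
    if (!k %in% names(cfg)) stop("unknown config key '", k, "'")
    cfg[[k]] <- ov[[k]]
  }
  cfg
}

#' @describeIn runConfig Write a config as flat key=value text.
#' @param cfg Config list.
#' @param file Path.
#' @export
writeRunConfig <- function(cfg, file) {
  writeLines(c("# backtralign run configuration",
               sprintf("%s=%s", names(cfg),
                       vapply(cfg, function(v) format(v, digits = 17),
                              character(1)))), file)
}

#' @describeIn runConfig Read a key=value config file.
#' @export
readRunConfig <- function(file) {
  lines <- grep("^#", readLines(file), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- runConfig()
  for (p in kv) {
    k <- p[1]; v <- paste(p[-1], collapse = "=")
    if (!k %in% names(cfg)) stop("unknown config key '", k, "'")
    cfg[[k]] <- if (is.numeric(cfg[[k]])) as.numeric(v)
    else if (is.logical(cfg[[k]])) as.logical(v)
    else v
  }
  cfg
}

#' Read the query sequence from a FASTA file
#'
#' Accepts protein or DNA FASTA (wrapped lines, multi-record); by default the
#' first record is used, or the record whose ID matches \code{id}. The
#' alphabet is auto-detected unless forced.
#'
#' @param file Path.
#' @param id Optional record ID.
#' @param alphabet \code{"auto"}, \code{"protein"} or \code{"dna"}.
#' @return List with \code{seq} (character) and \code{type}.
#' @export
readFastaSequence <- function(file, id = NULL, alphabet = "auto") {
  ss <- Biostrings::readBStringSet(file)
  if (!length(ss)) stop("no records in ", file)
  k <- 1L
  if (!is.null(id)) {
    hit <- which(vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
                 == id)
    if (!length(hit)) stop("no record with ID '", id, "' in ", file)
    k <- hit[1]
  }
  s <- toupper(as.character(ss[[k]]))
  type <- if (alphabet != "auto") alphabet else {
    if (grepl("^[ACGTUN]+$", s)) "dna" else "protein"
  }
  if (type == "dna") s <- gsub("U", "T", s)
  list(seq = s, type = type, id = names(ss)[k])
}

.log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message(...)
}

#' Run the full alignment pipeline
#'
#' Builds or loads the score matrix, back-translates the two input sequences
#' (single-path graphs for DNA input), optionally loads a Gumbel calibration,
#' aligns in the requested orientation(s) and returns a report: the
#' alignment(s), the rendered text and a flat machine-readable record.
#'
#' @param config List from \code{\link{runConfig}} (or a config file path).
#' @param fastaA,fastaB Paths to the two input FASTA files.
#' @param idA,idB Optional record IDs.
#' @return List with elements \code{alignments} (list of
#'   \linkS4class{AlignmentResult}), \code{report} (character vector),
#'   \code{record} (named list) and \code{config}.
#' @export
runPipeline <- function(config, fastaA, fastaB, idA = NULL, idB = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- config
  .log(cfg, "reading inputs")
  a <- readFastaSequence(fastaA, idA)
  b <- readFastaSequence(fastaB, idB)

  .log(cfg, "building score matrix (", cfg$model, ", theta=", cfg$theta, ")")
  pi <- if (nzchar(cfg$piFile)) readCodonFrequencies(cfg$piFile) else
    uniformCodonFrequencies()
  dnaMode <- a$type == "dna" && b$type == "dna"
  if (dnaMode) {
    scores <- dnaScoreMatrix()
    gA <- dnaGraph(a$seq); gB <- dnaGraph(b$seq)
  } else {
    if (a$type != b$type)
      stop("mixed DNA/protein input is not supported; supply two proteins ",
           "or two DNA sequences")
    model <- if (cfg$model == "empirical") {
      if (!nzchar(cfg$empiricalFile))
        stop("model=empirical requires empiricalFile")
      loadEmpiricalMatrix(cfg$empiricalFile, pi)
    } else mechanisticModel(cfg$theta, cfg$omega, cfg$kappa, pi)
    scores <- condenseScoreMatrix(buildScoreMatrix(model, pi = pi))
    gA <- buildGraph(a$seq, TRUE); gB <- buildGraph(b$seq, TRUE)
  }

  calibration <- NULL
  if (nzchar(cfg$calibrationFile)) {
    if (!file.exists(cfg$calibrationFile))
      stop("calibration file '", cfg$calibrationFile, "' not found; ",
           "run the calibrate subcommand (or calibrateAll()) first")
    calibration <- readCalibration(cfg$calibrationFile)
  }

  gaps <- gapParams(cfg$singleGapPenalty, cfg$tripleGapPenalty)
  doAlign <- function(ga, gb) {
    if (cfg$memoryMode == "cutpoint")
      alignLinearSpace(ga, gb, scores, gaps, cfg$maxFrameshifts,
                       cfg$cutWidth)
    else align(ga, gb, scores, gaps, cfg$maxFrameshifts)
  }
  .log(cfg, "aligning")
  alignments <- list()
  if (cfg$orientation %in% c("forward", "both"))
    alignments$forward <- doAlign(gA, gB)
  if (cfg$orientation %in% c("reverse", "both"))
    alignments$reverse <- doAlign(gA, reverseComplement(gB))
  if (!is.null(calibration) && !dnaMode)
    alignments <- lapply(alignments, applyCalibration, calibration)

  report <- unlist(lapply(names(alignments), function(o)
    c(paste0("== ", o, " alignment =="),
      formatAlignment(alignments[[o]]), "")))
  record <- list(
    idA = a$id, idB = b$id, typeA = a$type, typeB = b$type,
    model = cfg$model, theta = cfg$theta, omega = cfg$omega,
    kappa = cfg$kappa, singleGapPenalty = cfg$singleGapPenalty,
    tripleGapPenalty = cfg$tripleGapPenalty,
    maxFrameshifts = cfg$maxFrameshifts, seed = cfg$seed,
    scores = lapply(alignments, function(x) x@score),
    evalues = lapply(alignments, function(x) x@evalue),
    frameshifts = lapply(alignments, function(x) x@frameshifts))
  list(alignments = alignments, report = report, record = record,
       config = cfg)
}
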