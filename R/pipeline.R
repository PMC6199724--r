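#' Read a pipeline configuration file
#'
#' YAML (or the key-value subset of it) with sections `primers` (forward,
#' reverse, max_mismatches), `barcodes` (list of sample/forward/reverse),
#' `filters` (min_passes, min_length, max_length, max_ee, ee_inclusive,
#' host_fasta, screen_fraction), `clustering` (id_threshold, chim2_fasta)
#' and `seed`. Missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return Nested list of configuration values.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

.cfgGet <- function(cfg, path, default) {
  x <- cfg
  for (k in path) {
    if (is.null(x[[k]])) return(default)
    x <- x[[k]]
  }
  x
}

#' Run the pre-clustering cascade
#'
#' Applies, in order: demultiplex (when barcodes are configured), pass-count
#' filter, length filter, host screen (when a host reference is configured),
#' and primer matching/orientation/trimming. The expected-error filter is
#' deliberately not applied here: EE thresholds only gate the clustering
#' input, while abundance counting uses all primary-filtered reads.
#'
#' @param reads A [CcsReadSet-class] or FASTQ path.
#' @param config List from [readPipelineConfig()] (or an empty list for
#'   defaults).
#' @param barcodes Optional barcode data.frame (overrides config).
#' @param host Optional host reference (overrides config).
#' @param primers Optional [primerConfig()] (overrides config).
#' @return List with `reads` (filtered, oriented, trimmed), `report`
#'   (per-stage data.frame), and `tags` (per-read fail reason, NA = passed).
#' @export
runPreclustering <- function(reads, config = list(), barcodes = NULL,
                             host = NULL, primers = NULL) {
  if (is.character(reads)) reads <- readFastq(reads)
  if (is.null(primers)) {
    primers <- primerConfig(
      forward = .cfgGet(config, c("primers", "forward"),
                        DEFAULT_FORWARD_PRIMER),
      reverse = .cfgGet(config, c("primers", "reverse"),
                        DEFAULT_REVERSE_PRIMER),
      maxMismatches = .cfgGet(config, c("primers", "max_mismatches"), 2L))
  }
  if (is.null(barcodes)) {
    bc <- .cfgGet(config, "barcodes", NULL)
    if (!is.null(bc))
      barcodes <- do.call(rbind, lapply(bc, as.data.frame))
  }
  if (is.null(host))
    host <- .cfgGet(config, c("filters", "host_fasta"), NULL)

  tags <- setNames(rep(NA_character_, length(reads)), readIds(reads))
  stages <- list()
  cur <- reads
  if (!is.null(barcodes)) {
    dm <- demultiplex(cur, barcodes,
                      maxMismatches = .cfgGet(config,
                                              c("filters",
                                                "barcode_mismatches"), 1L))
    tags[names(dm$tags)] <- dm$tags
    stages$demultiplex <- list(pass = dm$assigned, fail = dm$unassigned)
    cur <- dm$assigned
  }
  fp <- filterByPasses(cur, .cfgGet(config, c("filters", "min_passes"), 5L))
  tags[names(fp$tags)[!is.na(fp$tags)]] <- fp$tags[!is.na(fp$tags)]
  stages$passes <- fp
  cur <- fp$pass
  fl <- filterByLength(cur,
                       .cfgGet(config, c("filters", "min_length"), 500L),
                       .cfgGet(config, c("filters", "max_length"), 2000L))
  tags[names(fl$tags)[!is.na(fl$tags)]] <- fl$tags[!is.na(fl$tags)]
  stages$length <- fl
  cur <- fl$pass
  if (!is.null(host)) {
    hs <- hostScreen(cur, host,
                     screenFraction = .cfgGet(config,
                                              c("filters",
                                                "screen_fraction"), 0.5))
    tags[names(hs$tags)[!is.na(hs$tags)]] <- hs$tags[!is.na(hs$tags)]
    stages$host <- list(pass = hs$nonHost, fail = hs$host)
    cur <- hs$nonHost
  }
  pm <- matchAndTrimPrimers(cur, primers)
  tags[names(pm$tags)[!is.na(pm$tags)]] <- pm$tags[!is.na(pm$tags)]
  stages$primer <- pm
  list(reads = pm$pass, report = filterReport(stages), tags = tags)
}

#' Run the clustering phase
#'
#' EE-thresholds the clustering input, dereplicates, greedy-clusters with
#' the de novo chimera filter (CHIM1), optionally applies the
#' reference-based CHIM2 filter, optionally classifies the centroids, and
#' quantifies OTU abundances by mapping the full (non-EE-thresholded) read
#' set back onto the final centroids.
#'
#' @param reads Pre-clustered reads from [runPreclustering()] (the full
#'   filtered set).
#' @param config Configuration list.
#' @param chim2Reference Optional reference set for CHIM2.
#' @param classifier Optional "KmerClassifier" for centroid classification.
#' @param seed Seed for classifier bootstraps.
#' @return An [OtuSet-class] with counts (and taxonomy when a classifier is
#'   given); attribute "eeReport" records the EE gate.
#' @export
runClustering <- function(reads, config = list(), chim2Reference = NULL,
                          classifier = NULL, seed = NULL) {
  maxEE <- .cfgGet(config, c("clustering", "max_ee"), 1.0)
  inclusive <- .cfgGet(config, c("clustering", "ee_inclusive"), TRUE)
  idThr <- .cfgGet(config, c("clustering", "id_threshold"), 0.97)
  fe <- filterByEE(reads, maxEE = maxEE, inclusive = inclusive)
  if (!length(fe$pass))
    stop("no reads pass the EE threshold; lower the stringency or check ",
         "input qualities")
  uniques <- dereplicate(fe$pass)
  otus <- greedyCluster(uniques, idThreshold = idThr)
  if (!is.null(chim2Reference))
    otus <- chimeraRefCheck(otus, chim2Reference)
  if (!is.null(classifier)) {
    tax <- classifyReads(centroids(otus), classifier, seed = seed)
    otus@taxonomy <- tax
  }
  otus <- mapReadsToCentroids(reads, otus, idThreshold = idThr)
  attr(otus, "eeReport") <- filterReport(list(ee = fe))
  otus
}

#' Assemble a reproducible run manifest
#'
#' @param config Config snapshot.
#' @param seed Seed used.
#' @param reports Named list of filter-report data.frames.
#' @param outputs Character vector of output file paths.
#' @param path Optional JSON output path.
#' @return Manifest list (invisibly written as JSON when `path` given).
#' @export
runManifest <- function(config = list(), seed = NA_integer_,
                        reports = list(), outputs = character(0),
                        path = NULL) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop(sprintf("manifest lists missing output '%s'", missing[1]))
  man <- list(tool = "fl16s",
              version = as.character(utils::packageVersion("fl16s")),
              seed = seed, config = config, reports = reports,
              outputs = outputs)
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(man)
}
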