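#' @include AllClasses.R
NULL

#' Render and parse stratum labels
#'
#' Stratum labels follow the field's convention: disease names finishing in
#' lowercase `f` are female strata, those finishing in lowercase `m` male
#' strata, and labels with all characters uppercase the pool of the two
#' sexes.  `renderStratumLabel()` produces a label from its parts;
#' `parseStratumLabel()` inverts it, rejecting malformed labels.
#'
#' @param diseaseCode uppercase disease code, e.g. `"DLB"`.
#' @param sex one of `"male"`, `"female"`, `"pooled"`.
#' @param label a stratum label string such as `"DLBm"`, `"ADf"` or `"MS"`.
#' @return `renderStratumLabel()`: a label string.  `parseStratumLabel()`:
#'   a list with elements `diseaseCode` and `sex`.
#' @examples
#' renderStratumLabel("AD", "female")   # "ADf"
#' parseStratumLabel("DLBm")            # DLB, male
#' parseStratumLabel("MS")              # MS, pooled
#' @export
renderStratumLabel <- function(diseaseCode, sex = c("pooled", "male", "female")) {
  sex <- match.arg(sex)
  if (!grepl("^[A-Z][A-Z0-9]*$", diseaseCode))
    stop("'diseaseCode' must be all-uppercase (got '", diseaseCode, "')")
  paste0(diseaseCode, switch(sex, male = "m", female = "f", pooled = ""))
}

#' @rdname renderStratumLabel
#' @export
parseStratumLabel <- function(label) {
  if (length(label) != 1L || is.na(label) || !nzchar(label))
    stop("'label' must be a single non-empty string")
  if (grepl("^[A-Z][A-Z0-9]*$", label))
    return(list(diseaseCode = label, sex = "pooled"))
  if (grepl("^[A-Z][A-Z0-9]*[fm]$", label)) {
    suffix <- substring(label, nchar(label))
    return(list(diseaseCode = substring(label, 1L, nchar(label) - 1L),
                sex = if (suffix == "f") "female" else "male"))
  }
  stop("malformed stratum label '", label,
       "': expected all-uppercase (pooled) or uppercase + 'f'/'m' suffix")
}

#' Construct an incidence dataset
#'
#' @param diseaseCode,sex,studyId identifying fields.
#' @param bins `data.frame` with columns `ageStart`, `ageEnd`, `incidence`
#'   (per 100,000 person-years); rows are sorted by `ageStart`.
#' @return an [IncidenceDataset-class].
#' @export
IncidenceDataset <- function(diseaseCode, sex, studyId, bins) {
  bins <- as.data.frame(bins)[c("ageStart", "ageEnd", "incidence")]
  bins <- bins[order(bins$ageStart), , drop = FALSE]
  rownames(bins) <- NULL
  new("IncidenceDataset", diseaseCode = diseaseCode, sex = sex,
      studyId = as.character(studyId), bins = bins)
}

#' @rdname IncidenceDataset
#' @param datasets a list of [IncidenceDataset-class] objects.
#' @export
IncidencePanel <- function(datasets = list()) {
  ans <- new("IncidencePanel", S4Vectors::SimpleList(datasets))
  names(ans) <- vapply(datasets, function(d)
    paste(stratumLabel(d), studyId(d), sep = "/"), character(1))
  ans
}

.PANEL_COLS <- c("disease", "sex", "study_id", "age_start", "age_end",
                 "incidence")

#' Read and write age-stratified incidence tables
#'
#' The on-disk dialect is comma-separated UTF-8 text with a mandatory
#' header `disease,sex,study_id,age_start,age_end,incidence`; age bins are
#' half-open `[start, end)` in years and incidence is per 100,000
#' person-years.  Rows are grouped into one dataset per
#' (disease, sex, study) triple.  Validation failures (missing columns,
#' negative incidence, overlapping bins) are reported with the offending
#' row numbers of the source file.
#'
#' @param path path to a CSV file.
#' @param panel an [IncidencePanel-class] or list of datasets to write.
#' @return `readIncidenceTable()` returns an [IncidencePanel-class];
#'   `writeIncidenceTable()` returns `path` invisibly.
#' @examples
#' spec <- diseaseSpec("HD", nTrue = 2L, backgroundRiskU = 1e-4,
#'                     ageMin = 15, ageMax = 80)
#' p <- generatePanel(list(spec), seed = 1L)
#' f <- tempfile(fileext = ".csv")
#' writeIncidenceTable(p, f)
#' p2 <- readIncidenceTable(f)
#' length(p2)
#' @export
readIncidenceTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.PANEL_COLS, names(tab))
  if (length(missing))
    stop("incidence table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(tab))
    return(IncidencePanel(list()))
  tab$.row <- seq_len(nrow(tab)) + 1L   # file line numbers (header = line 1)
  if (any(bad <- !(tab$sex %in% .SEXES)))
    stop("invalid sex value(s) at row(s) ",
         paste(tab$.row[bad], collapse = ", "),
         " (expected male/female/pooled)")
  if (any(bad <- tab$incidence < 0))
    stop("negative incidence at row(s) ", paste(tab$.row[bad], collapse = ", "))
  if (any(bad <- tab$age_start >= tab$age_end))
    stop("age_start >= age_end at row(s) ",
         paste(tab$.row[bad], collapse = ", "))
  key <- paste(tab$disease, tab$sex, tab$study_id, sep = "\r")
  groups <- split(tab, key)
  datasets <- lapply(groups, function(g) {
    g <- g[order(g$age_start), , drop = FALSE]
    if (nrow(g) >= 2L) {
      overlap <- which(g$age_end[-nrow(g)] > g$age_start[-1L] + 1e-9)
      if (length(overlap))
        stop("overlapping age bins for ", g$disease[1L], "/", g$sex[1L], "/",
             g$study_id[1L], " at rows ",
             paste(sort(c(g$.row[overlap], g$.row[overlap + 1L])),
                   collapse = ", "))
    }
    IncidenceDataset(g$disease[1L], g$sex[1L], g$study_id[1L],
                     data.frame(ageStart = g$age_start, ageEnd = g$age_end,
                                incidence = g$incidence))
  })
  ord <- order(vapply(datasets, stratumLabel, character(1)),
               vapply(datasets, studyId, character(1)))
  IncidencePanel(unname(datasets[ord]))
}

#' @rdname readIncidenceTable
#' @export
writeIncidenceTable <- function(panel, path) {
  rows <- lapply(panel, function(d) {
    b <- bins(d)
    data.frame(disease = diseaseCode(d), sex = sexStratum(d),
               study_id = studyId(d), age_start = b$ageStart,
               age_end = b$ageEnd, incidence = b$incidence)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Registry IDs of pooled AD datasets excluded from the recalculated model
#'
#' Seven pooled-sex Alzheimer's disease datasets dropped from the source
#' registry: five with male and female counterpart datasets present
#' (AD-61, AD-62, AD-68, AD-71, AD-78) and two small ones without
#' sex-annotated counterparts (AD-60, AD-82).
#'
#' @export
excludedRegistryIds <- function() {
  c("AD-60", "AD-61", "AD-62", "AD-68", "AD-71", "AD-78", "AD-82")
}

#' Apply the dataset-registry exclusion rule
#'
#' Removes pooled-sex datasets of a disease when male and female
#' counterpart datasets from the same study exist (the general counterpart
#' rule), and additionally any dataset whose study ID appears on an
#' explicit exclusion list.  Sex-annotated datasets are never removed.
#' Removals are reported via `message()` with their reasons and are
#' attached as the `"removed"` attribute of the result.
#'
#' @param panel an [IncidencePanel-class].
#' @param counterpartRule logical, apply the pooled-with-counterparts rule.
#' @param excludeIds character vector of study IDs to drop outright;
#'   defaults to [excludedRegistryIds()].
#' @param verbose emit one message per removal.
#' @return the filtered [IncidencePanel-class].
#' @export
filterRegistry <- function(panel, counterpartRule = TRUE,
                           excludeIds = excludedRegistryIds(),
                           verbose = TRUE) {
  if (!length(panel)) return(panel)
  disease <- vapply(panel, diseaseCode, character(1))
  sex <- vapply(panel, sexStratum, character(1))
  study <- vapply(panel, studyId, character(1))
  keep <- rep(TRUE, length(panel))
  reason <- character(length(panel))
  listed <- study %in% excludeIds
  keep[listed] <- FALSE
  reason[listed] <- "on the registry exclusion list"
  if (counterpartRule) {
    for (i in which(keep & sex == "pooled")) {
      hasM <- any(disease == disease[i] & study == study[i] & sex == "male")
      hasF <- any(disease == disease[i] & study == study[i] & sex == "female")
      if (hasM && hasF) {
        keep[i] <- FALSE
        reason[i] <- "pooled dataset with male and female counterparts"
      }
    }
  }
  if (verbose && any(!keep))
    for (i in which(!keep))
      message("filterRegistry: removing ", stratumLabel(panel[[i]]), "/",
              study[i], " (", reason[i], ")")
  out <- IncidencePanel(unname(as.list(panel)[keep]))
  attr(out, "removed") <- data.frame(
    stratum = vapply(as.list(panel)[!keep], stratumLabel, character(1)),
    study_id = study[!keep], reason = reason[!keep])
  out
}
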