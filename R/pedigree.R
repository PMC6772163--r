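# Pedigree container and file dialect.
#
# File dialect (version 1): tab-separated, header mandatory, "." for
# missing. Columns: family_id, member_id, father_id, mother_id,
# sex (1 = male, 2 = female), genotype (0 = untyped, 1 = noncarrier,
# 2 = carrier), proband (0/1), phenotype (0 = unaffected,
# 1 = breast cancer, 2 = ovarian cancer, 3 = other cancer), age_dx,
# age_last, surgery_type (mastectomy | oophorectomy), surgery_age,
# test_age (age inferred from genotyping test date, used when age_last is
# missing).

ped_columns <- function() {
  c("family_id", "member_id", "father_id", "mother_id", "sex", "genotype",
    "proband", "phenotype", "age_dx", "age_last", "surgery_type",
    "surgery_age", "test_age")
}

#' Construct a validated pedigree
#'
#' @param members Data frame with (at least) columns `member_id`,
#'   `father_id`, `mother_id`, `sex` (`"female"`/`"male"`), `genotype`
#'   (`"carrier"`/`"noncarrier"`/`"untyped"`), `proband` (logical),
#'   `phenotype` (`"unaffected"`, `"breast_cancer"`, `"ovarian_cancer"`,
#'   `"other"`), and optional numeric `age_dx`, `age_last`, `surgery_age`,
#'   `test_age` and character `surgery_type`. Both parents must be given or
#'   both missing; parents must appear in the table.
#' @param family_id Optional label.
#' @return An object of class `mf_pedigree`.
#' @export
pedigree <- function(members, family_id = "FAM1") {
  m <- as.data.frame(members, stringsAsFactors = FALSE)
  for (col in c("age_dx", "age_last", "surgery_age", "test_age"))
    if (!col %in% names(m)) m[[col]] <- NA_real_
  if (!"surgery_type" %in% names(m)) m$surgery_type <- NA_character_
  if (!"proband" %in% names(m)) m$proband <- FALSE
  need <- c("member_id", "father_id", "mother_id", "sex", "genotype",
            "proband", "phenotype")
  if (!all(need %in% names(m)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  m$member_id <- as.character(m$member_id)
  m$father_id <- as.character(m$father_id)
  m$mother_id <- as.character(m$mother_id)
  if (anyDuplicated(m$member_id)) stop("duplicate member_id", call. = FALSE)
  stopifnot(all(m$sex %in% c("female", "male")),
            all(m$genotype %in% c("carrier", "noncarrier", "untyped")),
            all(m$phenotype %in% c("unaffected", "breast_cancer",
                                   "ovarian_cancer", "other")))
  has_f <- !is.na(m$father_id)
  has_m <- !is.na(m$mother_id)
  if (any(has_f != has_m))
    stop("members must have both parents or neither", call. = FALSE)
  miss <- setdiff(c(m$father_id[has_f], m$mother_id[has_m]), m$member_id)
  if (length(miss))
    stop("parent id(s) not in pedigree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (sum(m$proband) != 1L)
    stop("pedigree must have exactly one proband", call. = FALSE)
  if (is.na(topological_order(m))[1])
    stop("pedigree is cyclic (a member is its own ancestor)", call. = FALSE)
  ages <- c(m$age_dx, m$age_last, m$surgery_age, m$test_age)
  if (any(ages < 0, na.rm = TRUE)) stop("negative ages", call. = FALSE)
  rownames(m) <- NULL
  structure(list(family_id = family_id, members = m), class = "mf_pedigree")
}

# Kahn ordering; NA if cyclic.
topological_order <- function(m) {
  ids <- m$member_id
  parents <- function(i) stats::na.omit(c(m$father_id[i], m$mother_id[i]))
  placed <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i)
      all(parents(i) %in% placed), logical(1))]
    if (!length(ready)) return(NA_character_)
    placed <- c(placed, ids[ready])
    remaining <- setdiff(remaining, ready)
  }
  placed
}

founder_ids <- function(ped) {
  m <- ped$members
  m$member_id[is.na(m$father_id)]
}

# All ancestors of a member (ids), excluding the member itself.
ancestor_ids <- function(m, id) {
  out <- character(0)
  frontier <- id
  while (length(frontier)) {
    i <- match(frontier, m$member_id)
    ps <- stats::na.omit(c(m$father_id[i], m$mother_id[i]))
    ps <- setdiff(ps, out)
    out <- c(out, ps)
    frontier <- ps
  }
  out
}

# Consanguineous matings (mates sharing an ancestor, or one being the
# other's ancestor) create genotype loops; reject them.
check_no_loops <- function(ped) {
  m <- ped$members
  kids <- which(!is.na(m$father_id))
  couples <- unique(data.frame(f = m$father_id[kids], mo = m$mother_id[kids],
                               stringsAsFactors = FALSE))
  for (i in seq_len(nrow(couples))) {
    f <- couples$f[i]; mo <- couples$mo[i]
    af <- c(f, ancestor_ids(m, f))
    am <- c(mo, ancestor_ids(m, mo))
    if (length(intersect(af, am)))
      stop("pedigree contains a consanguineous mating (", f, " x ", mo,
           "); looped pedigrees are not supported", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.mf_pedigree <- function(x, ...) {
  m <- x$members
  cat(sprintf("<pedigree %s> %d members, %d genotyped, %d affected\n",
              x$family_id, nrow(m), sum(m$genotype != "untyped"),
              sum(m$phenotype %in% c("breast_cancer", "ovarian_cancer"))))
  invisible(x)
}

#' Read pedigrees from a tab-separated file
#'
#' See the dialect description at the top of this file's help index; one
#' file may hold several families.
#'
#' @param path File path.
#' @return A named list of [pedigree()] objects, one per `family_id`.
#' @export
read_pedigree_file <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                    colClasses = "character")
  if (!all(ped_columns() %in% names(raw)))
    stop("pedigree file must have columns: ",
         paste(ped_columns(), collapse = ", "), call. = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  sex_dec <- c(`1` = "male", `2` = "female")
  gt_dec <- c(`0` = "untyped", `1` = "noncarrier", `2` = "carrier")
  ph_dec <- c(`0` = "unaffected", `1` = "breast_cancer",
              `2` = "ovarian_cancer", `3` = "other")
  if (any(!raw$sex %in% names(sex_dec)) ||
      any(!raw$genotype %in% names(gt_dec)) ||
      any(!raw$phenotype %in% names(ph_dec)))
    stop("bad sex/genotype/phenotype code in pedigree file", call. = FALSE)
  df <- data.frame(
    family_id = raw$family_id, member_id = raw$member_id,
    father_id = raw$father_id, mother_id = raw$mother_id,
    sex = unname(sex_dec[raw$sex]), genotype = unname(gt_dec[raw$genotype]),
    proband = raw$proband == "1", phenotype = unname(ph_dec[raw$phenotype]),
    age_dx = num(raw$age_dx), age_last = num(raw$age_last),
    surgery_type = raw$surgery_type, surgery_age = num(raw$surgery_age),
    test_age = num(raw$test_age), stringsAsFactors = FALSE)
  out <- lapply(split(df, df$family_id), function(fam)
    pedigree(fam[setdiff(names(fam), "family_id")],
             family_id = fam$family_id[1]))
  out[unique(df$family_id)]
}

#' Write pedigrees to the tab-separated dialect
#'
#' @param peds A [pedigree()] or list of pedigrees.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_file <- function(peds, path) {
  if (inherits(peds, "mf_pedigree")) peds <- list(peds)
  sex_enc <- c(male = "1", female = "2")
  gt_enc <- c(untyped = "0", noncarrier = "1", carrier = "2")
  ph_enc <- c(unaffected = "0", breast_cancer = "1", ovarian_cancer = "2",
              other = "3")
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  rows <- lapply(peds, function(p) {
    m <- p$members
    data.frame(family_id = p$family_id, member_id = m$member_id,
               father_id = fmt(m$father_id), mother_id = fmt(m$mother_id),
               sex = unname(sex_enc[m$sex]),
               genotype = unname(gt_enc[m$genotype]),
               proband = ifelse(m$proband, "1", "0"),
               phenotype = unname(ph_enc[m$phenotype]),
               age_dx = fmt(m$age_dx), age_last = fmt(m$age_last),
               surgery_type = fmt(m$surgery_type),
               surgery_age = fmt(m$surgery_age), test_age = fmt(m$test_age),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
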