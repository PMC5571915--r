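# Missense variant (nsSNP) handling: humsavar-dialect parsing, sequence to
# structure numbering reconciliation, structural annotation and the region
# census.

.variant_categories <- c("DISEASE", "POLYMORPHISM", "UNCLASSIFIED")

.category_map <- c(
  "Disease" = "DISEASE", "Polymorphism" = "POLYMORPHISM",
  "Unclassified" = "UNCLASSIFIED"
)
# post-2014 humsavar vocabulary, mapped onto the classic three categories
.category_map_modern <- c(
  "LP/P" = "DISEASE", "P" = "DISEASE", "LP" = "DISEASE",
  "LB/B" = "POLYMORPHISM", "B" = "POLYMORPHISM", "LB" = "POLYMORPHISM",
  "US" = "UNCLASSIFIED"
)

#' Parse a humsavar-dialect variant table
#'
#' Parses whitespace-separated lines of the UniProt humsavar dialect: gene
#' symbol, protein accession, variant FTId, substitution (`p.Xaa123Yaa`),
#' category token, dbSNP id, phenotype text. Header or non-variant lines
#' (no `p.` substitution token) are skipped. Categories map
#' Disease/Polymorphism/Unclassified onto `DISEASE` / `POLYMORPHISM` /
#' `UNCLASSIFIED`; with `modern_categories = TRUE` the newer LP/P, LB/B and
#' US tokens are mapped onto the same three classes. Substitutions whose
#' wild-type and mutant residues are identical, or that cannot be parsed,
#' are skipped with a warning (`strict = TRUE` raises an error instead).
#'
#' @param text Character vector of lines (or one string with newlines).
#' @param strict Error on unparseable substitutions instead of skipping.
#' @param modern_categories Accept the post-2014 category vocabulary.
#' @return A tibble: `gene`, `accession`, `ftid`, `position`, `wt_aa`,
#'   `mut_aa`, `category` (factor), `dbsnp`, `phenotype`.
#' @export
parse_variant_table <- function(text, strict = FALSE,
                                modern_categories = FALSE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[grepl("p\\.[A-Za-z]{3}\\d+[A-Za-z]{3}", lines)]
  if (length(lines) == 0) {
    return(tibble(gene = character(), accession = character(),
                  ftid = character(), position = integer(),
                  wt_aa = character(), mut_aa = character(),
                  category = factor(character(),
                                    levels = .variant_categories),
                  dbsnp = character(), phenotype = character()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  cmap <- .category_map
  if (modern_categories) cmap <- c(cmap, .category_map_modern)
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 5) {
      if (strict) abort(paste0("unparseable variant line: ", lines[i]))
      warn(paste0("skipping malformed variant line: ", lines[i]))
      return(NULL)
    }
    sub <- f[4]
    m <- regmatches(sub, regexec("^p\\.([A-Za-z]{3})(\\d+)([A-Za-z]{3})$",
                                 sub))[[1]]
    if (length(m) != 4) {
      if (strict) abort(paste0("unparseable substitution: ", sub))
      warn(paste0("skipping unparseable substitution: ", sub))
      return(NULL)
    }
    wt3 <- toupper(m[2]); mut3 <- toupper(m[4])
    wt <- unname(.aa_three_to_one[wt3])
    mut <- unname(.aa_three_to_one[mut3])
    if (is.na(wt) || is.na(mut)) {
      if (strict) abort(paste0("unknown amino acid in substitution: ", sub))
      warn(paste0("skipping substitution with unknown amino acid: ", sub))
      return(NULL)
    }
    if (wt == mut) {
      if (strict) abort(paste0("silent substitution: ", sub))
      warn(paste0("skipping silent substitution: ", sub))
      return(NULL)
    }
    cat_tok <- f[5]
    category <- unname(cmap[cat_tok])
    if (is.na(category)) {
      if (strict) abort(paste0("unknown variant category: ", cat_tok))
      warn(paste0("skipping variant with unknown category: ", cat_tok))
      return(NULL)
    }
    tibble(gene = f[1], accession = f[2], ftid = f[3],
           position = as.integer(m[3]), wt_aa = wt, mut_aa = mut,
           category = category,
           dbsnp = if (length(f) >= 6) f[6] else NA_character_,
           phenotype = if (length(f) >= 7) {
             paste(f[-(1:6)], collapse = " ")
           } else NA_character_)
  })
  out <- bind_rows(recs)
  if (nrow(out) == 0) {
    return(parse_variant_table(character(0)))
  }
  if (any(out$position < 1)) abort("variant position < 1")
  out$category <- factor(out$category, levels = .variant_categories)
  out
}

#' Read a humsavar-dialect variant file
#'
#' @param path Path to the file.
#' @inheritParams parse_variant_table
#' @return See [parse_variant_table()].
#' @export
read_humsavar <- function(path, strict = FALSE, modern_categories = FALSE) {
  parse_variant_table(readLines(path, warn = FALSE), strict = strict,
                      modern_categories = modern_categories)
}

#' Reconcile sequence numbering with structure numbering
#'
#' Globally aligns the one-letter sequence derived from a structure chain
#' to the full protein sequence (match 1, mismatch -1, gap open 5, gap
#' extend 0.5; the structure sequence is aligned end-to-end within the full
#' sequence). The map covers only aligned, identical positions. Maps whose
#' identity over the aligned span is below `min_identity` are rejected.
#'
#' @param uniprot_sequence Full protein sequence (one-letter string).
#' @param structure A [structure_model()].
#' @param chain Chain to map; defaults to the single chain present (an
#'   error if the structure has several and none is named).
#' @param min_identity Identity threshold over the aligned span.
#' @return A `numbering_map` tibble with columns `position` (sequence,
#'   1-based), `res_key`, `aa`; attributes `identity` and `alignment`.
#' @export
build_numbering_map <- function(uniprot_sequence, structure, chain = NULL,
                                min_identity = 0.95) {
  chains <- unique(structure$chain)
  if (is.null(chain)) {
    if (length(chains) > 1) {
      abort(paste0("structure has several chains (",
                   paste(chains, collapse = ","),
                   "); name the chain to map"))
    }
    chain <- chains[1]
  }
  res <- residues(structure) |> filter(.data$chain == !!chain)
  if (nrow(res) == 0) abort(paste0("no residues in chain ", chain))
  aa <- unname(.aa_three_to_one[res$resname])
  keep <- !is.na(aa)
  res <- res[keep, ]
  aa <- aa[keep]
  if (length(aa) == 0) abort("no standard amino acids in chain")
  struct_seq <- paste(aa, collapse = "")

  alphabet <- unique(c(names(.aa_one_to_three), "X",
                       strsplit(toupper(uniprot_sequence), "")[[1]]))
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = struct_seq, subject = toupper(uniprot_sequence),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  start_sub <- aln@subject@range@start

  pi_ <- 0L # index into structure residues
  si <- start_sub - 1L # sequence position
  map_pos <- integer(0)
  map_res <- integer(0)
  n_aligned <- 0L
  n_ident <- 0L
  for (k in seq_along(pat)) {
    p_gap <- pat[k] == "-"
    s_gap <- sub[k] == "-"
    if (!p_gap) pi_ <- pi_ + 1L
    if (!s_gap) si <- si + 1L
    if (!p_gap && !s_gap) {
      n_aligned <- n_aligned + 1L
      if (pat[k] == sub[k]) {
        n_ident <- n_ident + 1L
        map_pos <- c(map_pos, si)
        map_res <- c(map_res, pi_)
      }
    }
  }
  identity <- if (n_aligned > 0) n_ident / n_aligned else 0
  if (identity < min_identity) {
    abort(c(paste0("sequence/structure identity ", sprintf("%.3f", identity),
                   " below threshold ", min_identity),
            i = paste0("alignment: ", as.character(aln))))
  }
  out <- tibble(position = map_pos,
                res_key = res$res_key[map_res],
                aa = aa[map_res])
  structure(out,
            class = c("numbering_map", class(tibble())),
            identity = identity,
            chain = chain,
            source_id = attr(structure, "source_id"))
}

.evidence_levels <- c("STRUCTURE", "DOCKING", "BOTH", "NONE")

#' Annotate variants with their structural location
#'
#' Combined-evidence rule: a mapped variant is `INTERFACE` if its residue
#' is an interface residue in any complex-structure classification or an
#' extended-interface residue in any docking profile; otherwise it is
#' `CORE` or `NON_INTERFACE_SURFACE` by averaged rASA. It is a hot-spot iff
#' some docking profile flags the residue as a NIP hot-spot and its
#' location is `INTERFACE`. Variants whose position is not covered by any
#' numbering map, or whose mapped residue's amino acid disagrees with the
#' variant's wild type, are `UNMAPPED` with evidence `NONE` (the mismatch
#' is an error in strict mode).
#'
#' @param variants Tibble from [parse_variant_table()].
#' @param structure_labels A `residue_classification` (or `NULL`) from
#'   complex structures, keyed by `res_key`.
#' @param docking_profiles List of `nip_profile` objects (possibly empty).
#' @param map A `numbering_map` (for one accession), or a named list of
#'   maps keyed by accession.
#' @param core_cutoff rASA threshold for the core call.
#' @param strict Error on wild-type mismatches.
#' @return A `variant_annotation` tibble: the variant columns plus
#'   `res_key`, `location` (CORE / INTERFACE / NON_INTERFACE_SURFACE /
#'   UNMAPPED), `hotspot`, `evidence` (STRUCTURE / DOCKING / BOTH / NONE).
#' @export
annotate_variants <- function(variants, structure_labels = NULL,
                              docking_profiles = list(), map,
                              core_cutoff = 0.1, strict = FALSE) {
  if (inherits(docking_profiles, "nip_profile")) {
    docking_profiles <- list(docking_profiles)
  }
  maps <- if (inherits(map, "numbering_map")) {
    setNames(list(map), variants$accession[1] %||% "protein")
  } else map

  dock_tbl <- if (length(docking_profiles) > 0) {
    bind_rows(lapply(docking_profiles, as_tibble)) |>
      group_by(.data$res_key) |>
      summarise(dock_rasa = mean(.data$rasa, na.rm = TRUE),
                dock_interface = any(.data$extended_interface),
                dock_hotspot = any(.data$hotspot), .groups = "drop")
  } else NULL

  n <- nrow(variants)
  res_key <- rep(NA_character_, n)
  location <- rep("UNMAPPED", n)
  hotspot <- rep(FALSE, n)
  evidence <- rep("NONE", n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    m <- maps[[v$accession]] %||% maps[[1]]
    if (is.null(m)) next
    j <- match(v$position, m$position)
    if (is.na(j)) next
    if (m$aa[j] != v$wt_aa) {
      msg <- paste0("wild-type mismatch for ", v$accession, " p.", v$wt_aa,
                    v$position, v$mut_aa, ": structure has ", m$aa[j])
      if (strict) abort(msg)
      warn(paste0(msg, "; marking UNMAPPED"))
      next
    }
    key <- m$res_key[j]
    res_key[i] <- key
    s_row <- if (!is.null(structure_labels)) {
      structure_labels[structure_labels$res_key == key, , drop = FALSE]
    } else NULL
    in_struct <- !is.null(s_row) && nrow(s_row) > 0
    d_row <- if (!is.null(dock_tbl)) {
      dock_tbl[dock_tbl$res_key == key, , drop = FALSE]
    } else NULL
    in_dock <- !is.null(d_row) && nrow(d_row) > 0
    if (!in_struct && !in_dock) next
    struct_if <- in_struct && s_row$label[1] == "INTERFACE"
    dock_if <- in_dock && d_row$dock_interface[1]
    rasas <- c(if (in_struct) s_row$rasa[1],
               if (in_dock) d_row$dock_rasa[1])
    avg_rasa <- mean(rasas, na.rm = TRUE)
    location[i] <- if (struct_if || dock_if) {
      "INTERFACE"
    } else if (!is.na(avg_rasa) && avg_rasa < core_cutoff) {
      "CORE"
    } else {
      "NON_INTERFACE_SURFACE"
    }
    hotspot[i] <- location[i] == "INTERFACE" && in_dock &&
      isTRUE(d_row$dock_hotspot[1])
    evidence[i] <- if (in_struct && in_dock) "BOTH"
                   else if (in_struct) "STRUCTURE" else "DOCKING"
  }
  out <- variants |>
    mutate(res_key = res_key,
           location = factor(location,
                             levels = c(.location_levels, "UNMAPPED")),
           hotspot = hotspot,
           evidence = factor(evidence, levels = .evidence_levels))
  class(out) <- c("variant_annotation", class(out))
  out
}

#' Region census of residues and variants
#'
#' Tallies residues and annotated nsSNPs per structural region, in the
#' layout used for interaction-network surveys: residue counts (total,
#' core, interface, non-interacting surface, hot-spot, hot-spot at
#' interface) and per-category variant counts for the same regions.
#' Unmapped variants are excluded from the location counts and reported
#' under region `unmapped`.
#'
#' @param annotations A `variant_annotation` tibble (may be empty).
#' @param residue_labels Tibble with one row per residue: `label` and
#'   logical `hotspot` (optional, defaults to none).
#' @param context Label for this census (`"structural"`, `"docking"`,
#'   `"combined"`, or free text).
#' @return A `region_census` tibble: `context`, `group` (`residues` or a
#'   variant category), `region`, `count`.
#' @export
region_census <- function(annotations, residue_labels,
                          context = "structural") {
  residue_labels <- as_tibble(residue_labels)
  if (!"hotspot" %in% names(residue_labels)) residue_labels$hotspot <- FALSE
  lab <- as.character(residue_labels$label)
  res_counts <- tibble(
    context = context, group = "residues",
    region = c("total", "core", "interface", "non_interface", "hotspot",
               "hotspot_interface"),
    count = c(nrow(residue_labels),
              sum(lab == "CORE"),
              sum(lab == "INTERFACE"),
              sum(lab == "NON_INTERFACE_SURFACE"),
              sum(residue_labels$hotspot),
              sum(residue_labels$hotspot & lab == "INTERFACE")))
  snp_counts <- lapply(.variant_categories, function(cat) {
    a <- annotations[!is.na(annotations$category) &
                       annotations$category == cat, , drop = FALSE]
    loc <- as.character(a$location)
    tibble(
      context = context, group = cat,
      region = c("total", "core", "interface", "non_interface",
                 "hotspot_interface", "unmapped"),
      count = c(sum(loc != "UNMAPPED"),
                sum(loc == "CORE"),
                sum(loc == "INTERFACE"),
                sum(loc == "NON_INTERFACE_SURFACE"),
                sum(a$hotspot),
                sum(loc == "UNMAPPED")))
  })
  out <- bind_rows(c(list(res_counts), snp_counts))
  class(out) <- c("region_census", class(out))
  out
}

#' Look up one census count
#'
#' @param census A `region_census` tibble.
#' @param group `"residues"` or a variant category.
#' @param region Region name (`total`, `core`, `interface`,
#'   `non_interface`, `hotspot`, `hotspot_interface`, `unmapped`).
#' @return Integer count.
#' @export
census_count <- function(census, group, region) {
  hit <- census$count[census$group == group & census$region == region]
  if (length(hit) != 1) {
    abort(paste0("no unique census entry for group=", group,
                 ", region=", region))
  }
  hit
}

#' Write variant annotations or a census as TSV
#'
#' @param x A `variant_annotation` or `region_census` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
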