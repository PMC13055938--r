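# Identity normalization, hash tokens and deterministic record linkage.
#
# Two health systems are linked by (1) an identifier crosswalk, (2) exact
# agreement on normalized first name, last name, gender and birth date, or
# (3) a shared medical record number. The death-master extract is linked to
# resolved person clusters through five keyed hash tokens; tokens 1 and 2
# must match jointly, tokens 3, 4 and 5 each suffice alone.

SOURCES <- c("SYSTEM_A", "SYSTEM_B", "SSADMF")

.accents_from <- paste0(
  "\u00e1\u00e0\u00e2\u00e4\u00e3\u00e5\u00e7\u00e9\u00e8\u00ea\u00eb",
  "\u00ed\u00ec\u00ee\u00ef\u00f1\u00f3\u00f2\u00f4\u00f6\u00f5",
  "\u00fa\u00f9\u00fb\u00fc\u00fd\u00ff",
  "\u00c1\u00c0\u00c2\u00c4\u00c3\u00c5\u00c7\u00c9\u00c8\u00ca\u00cb",
  "\u00cd\u00cc\u00ce\u00cf\u00d1\u00d3\u00d2\u00d4\u00d6\u00d5",
  "\u00da\u00d9\u00db\u00dc\u00dd"
)
.accents_to <- paste0(
  "AAAAAACEEEEIIIINOOOOOUUUUYY",
  "AAAAAACEEEEIIIINOOOOOUUUUY"
)

#' Normalize a personal name for matching
#'
#' Folds Latin diacritics to ASCII, uppercases, and strips every
#' non-alphabetic character (spaces, hyphens, apostrophes, periods). Empty
#' input stays empty. All token construction and name matching operates on
#' this normal form, so case and punctuation differences never break a match.
#'
#' @param raw Character vector of raw names.
#' @return Character vector of normalized names (possibly empty strings).
#' @examples
#' normalize_name("O'Brien ")  # "OBRIEN"
#' normalize_name("jos\u00e9") # "JOSE"
#' @export
normalize_name <- function(raw) {
  x <- chartr(.accents_from, .accents_to, as.character(raw))
  x <- toupper(x)
  x <- gsub("[^A-Z]", "", x)
  x[is.na(raw)] <- ""
  x
}

# letter -> Soundex consonant class; 0 = vowel/Y separator, 7 = H/W (ignored,
# does not separate equal codes)
.sdx_code <- local({
  v <- integer(26)
  names(v) <- LETTERS
  v[c("B", "F", "P", "V")] <- 1L
  v[c("C", "G", "J", "K", "Q", "S", "X", "Z")] <- 2L
  v[c("D", "T")] <- 3L
  v["L"] <- 4L
  v[c("M", "N")] <- 5L
  v["R"] <- 6L
  v[c("A", "E", "I", "O", "U", "Y")] <- 0L
  v[c("H", "W")] <- 7L
  v
})

soundex_one <- function(name) {
  letters_i <- strsplit(name, "", fixed = TRUE)[[1]]
  codes <- .sdx_code[letters_i]
  out <- character(0)
  last <- codes[1] # the first letter's own class participates in collapsing
  if (length(codes) > 1) {
    for (k in codes[-1]) {
      if (k == 7L) next            # H/W: skipped, do not reset the run
      if (k == 0L) { last <- 0L; next } # vowel/Y: separator, resets the run
      if (k != last) out <- c(out, k)
      last <- k
      if (length(out) == 3L) break
    }
  }
  paste0(letters_i[1], paste(c(out, rep("0", 3L - length(out))), collapse = ""))
}

#' American Soundex code
#'
#' Encodes a normalized surname or given name as a letter plus three digits
#' under the American (NARA) Soundex rules: the first letter is retained;
#' remaining letters are coded into six consonant classes; vowels and Y are
#' dropped but separate repeated codes; H and W are dropped without
#' separating them; adjacent equal codes collapse (including against the
#' first letter's own class); the result is zero-padded or truncated to
#' three digits.
#'
#' @param name Character vector of normalized names (see [normalize_name()]);
#'   must contain only letters and be non-empty.
#' @return Character vector of 4-character Soundex codes.
#' @examples
#' soundex("WASHINGTON") # "W252"
#' soundex("PFISTER")    # "P236"
#' @export
soundex <- function(name) {
  name <- as.character(name)
  if (any(is.na(name)) || any(!nzchar(name))) {
    stop("soundex: empty or missing name cannot be encoded")
  }
  if (any(grepl("[^A-Za-z]", name))) {
    stop("soundex: names must be normalized (letters only); see normalize_name()")
  }
  name <- toupper(name)
  u <- unique(name)
  vapply(u, soundex_one, character(1), USE.NAMES = FALSE)[match(name, u)]
}

token_digest <- function(material, salt) {
  as.character(openssl::sha256(material, key = as.character(salt)))
}

# hash with de-duplication: records duplicated across registries (clean
# matched twins) share token material, so hash each distinct material once
token_digest_dedup <- function(material, salt) {
  u <- unique(material)
  if (length(u) == length(material)) return(token_digest(material, salt))
  token_digest(u, salt)[match(material, u)]
}

#' Build linkage hash tokens for a registry
#'
#' Emits up to five keyed 256-bit digests per record, each over kind-tagged,
#' separator-joined normalized fields:
#' \describe{
#'   \item{T1}{last name, first initial, gender, birth date}
#'   \item{T2}{Soundex last name, Soundex first name, gender, birth date}
#'   \item{T3}{last name, first name, gender, birth date}
#'   \item{T4}{SSN, gender, birth date}
#'   \item{T5}{SSN, first name}
#' }
#' T1-T3 require non-empty names, gender and birth date; T4-T5 additionally
#' (respectively, instead) require an SSN. Missing fields silently suppress
#' the affected tokens. Unknown gender is serialized as "U"; birth dates are
#' serialized ISO-8601. The digest is an HMAC-SHA256 keyed with `salt`, so
#' equal normalized inputs always produce equal digests and tokens are not
#' invertible without the key.
#'
#' @param records Data frame with columns `record_id`, `source`,
#'   `first_name`, `last_name`, `gender`, `birth_date`, and optionally `ssn`.
#' @param salt Character scalar keying the digest.
#' @return Data frame with columns `record_id`, `source`, `kind`
#'   (T1..T5), `digest`.
#' @export
TOKEN_KINDS <- c("T1", "T2", "T3", "T4", "T5")

# normalized field set shared by all token kinds
token_fields <- function(records) {
  n <- nrow(records)
  first <- normalize_name(records$first_name)
  last <- normalize_name(records$last_name)
  gender <- as.character(records$gender)
  gender[is.na(gender) | !gender %in% c("F", "M")] <- "U"
  bdate <- format(records$birth_date, "%Y-%m-%d")
  ssn <- if ("ssn" %in% names(records)) as.character(records$ssn) else rep(NA_character_, n)
  ssn[!is.na(ssn) & !grepl("^[0-9]{9}$", ssn)] <- NA_character_
  list(first = first, last = last, gender = gender, bdate = bdate, ssn = ssn)
}

# token material of one kind: list(idx = record rows emitting it, mat = the
# kind-tagged field string); processed one kind at a time to bound memory
token_material <- function(f, kind) {
  mk <- function(idx, ...) { # paste that stays empty for empty inputs
    list(idx = idx, mat = if (!length(idx)) character(0) else paste(..., sep = "|"))
  }
  has_name <- which(nzchar(f$first) & nzchar(f$last) & !is.na(f$bdate))
  switch(kind,
    T1 = {
      i <- has_name
      mk(i, "T1", f$last[i], substr(f$first[i], 1, 1), f$gender[i], f$bdate[i])
    },
    T2 = {
      i <- has_name
      mk(i, "T2", soundex(f$last[i]), soundex(f$first[i]), f$gender[i], f$bdate[i])
    },
    T3 = {
      i <- has_name
      mk(i, "T3", f$last[i], f$first[i], f$gender[i], f$bdate[i])
    },
    T4 = {
      i <- which(!is.na(f$ssn) & !is.na(f$bdate))
      mk(i, "T4", f$ssn[i], f$gender[i], f$bdate[i])
    },
    T5 = {
      i <- which(!is.na(f$ssn) & nzchar(f$first))
      mk(i, "T5", f$ssn[i], f$first[i])
    },
    stop("unknown token kind: ", kind)
  )
}

build_tokens <- function(records, salt) {
  stopifnot(is.data.frame(records),
            all(c("record_id", "source", "first_name", "last_name",
                  "gender", "birth_date") %in% names(records)))
  f <- token_fields(records)
  src <- as.character(records$source)
  parts <- lapply(TOKEN_KINDS, function(kind) {
    tm <- token_material(f, kind)
    data.frame(record_id = records$record_id[tm$idx],
               source = src[tm$idx],
               kind = rep(kind, length(tm$idx)),
               digest = token_digest_dedup(tm$mat, salt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

check_unique_ids <- function(registry, label) {
  dup <- duplicated(registry$record_id)
  if (any(dup)) {
    stop(sprintf("duplicate record_id in %s: %s", label,
                 paste(utils::head(unique(registry$record_id[dup]), 5), collapse = ", ")))
  }
}

# base-R many-to-many equi-join on a single key, returning index pairs
join_on_key <- function(key_a, key_b) {
  ok_a <- !is.na(key_a) & nzchar(key_a)
  ok_b <- !is.na(key_b) & nzchar(key_b)
  common_a <- ok_a & (key_a %in% key_b[ok_b])
  if (!any(common_a)) {
    return(data.frame(ia = integer(0), ib = integer(0)))
  }
  common_b <- ok_b & (key_b %in% key_a[common_a])
  da <- data.frame(ia = which(common_a), key = key_a[common_a], stringsAsFactors = FALSE)
  db <- data.frame(ib = which(common_b), key = key_b[common_b], stringsAsFactors = FALSE)
  m <- merge(da, db, by = "key")
  data.frame(ia = m$ia, ib = m$ib)
}

#' Link records across the two health systems
#'
#' A pair of records (one per system) is linked when any of three
#' deterministic rules fires: the identifier crosswalk lists the pair
#' (`XWALK`), the normalized first name, last name, gender and birth date all
#' agree exactly (`NAMEDOB`), or the medical record numbers agree (`MRN`).
#' The rules are disjunctive; every firing rule is reported as evidence.
#'
#' @param registry_A,registry_B Registry data frames (columns `record_id`,
#'   `first_name`, `last_name`, `gender`, `birth_date`, optional `mrn`).
#' @param crosswalk Optional data frame with columns `record_id_A`,
#'   `record_id_B`; rows referencing unknown record ids or containing
#'   missing values are rejected with their row index.
#' @return Data frame of pairwise links: `record_id_A`, `record_id_B`,
#'   `rule` in {XWALK, NAMEDOB, MRN}.
#' @export
link_cross_system <- function(registry_A, registry_B, crosswalk = NULL) {
  check_unique_ids(registry_A, "registry_A")
  check_unique_ids(registry_B, "registry_B")

  links <- list()
  if (!is.null(crosswalk)) {
    if (!all(c("record_id_A", "record_id_B") %in% names(crosswalk))) {
      stop("crosswalk must have columns record_id_A and record_id_B")
    }
    bad <- which(is.na(crosswalk$record_id_A) | is.na(crosswalk$record_id_B) |
                   !(crosswalk$record_id_A %in% registry_A$record_id) |
                   !(crosswalk$record_id_B %in% registry_B$record_id))
    if (length(bad)) {
      stop(sprintf("malformed crosswalk rows: %s",
                   paste(utils::head(bad, 10), collapse = ", ")))
    }
    if (nrow(crosswalk)) {
      links$xwalk <- data.frame(record_id_A = crosswalk$record_id_A,
                                record_id_B = crosswalk$record_id_B,
                                rule = "XWALK", stringsAsFactors = FALSE)
    }
  }

  namedob <- function(reg) {
    g <- as.character(reg$gender)
    g[is.na(g) | !g %in% c("F", "M")] <- "U"
    first <- normalize_name(reg$first_name)
    last <- normalize_name(reg$last_name)
    key <- paste(first, last, g, format(reg$birth_date, "%Y-%m-%d"), sep = "|")
    key[!nzchar(first) | !nzchar(last) | is.na(reg$birth_date)] <- NA_character_
    key
  }
  jn <- join_on_key(namedob(registry_A), namedob(registry_B))
  if (nrow(jn)) {
    links$namedob <- data.frame(record_id_A = registry_A$record_id[jn$ia],
                                record_id_B = registry_B$record_id[jn$ib],
                                rule = "NAMEDOB", stringsAsFactors = FALSE)
  }

  mrn_a <- if ("mrn" %in% names(registry_A)) as.character(registry_A$mrn) else rep(NA_character_, nrow(registry_A))
  mrn_b <- if ("mrn" %in% names(registry_B)) as.character(registry_B$mrn) else rep(NA_character_, nrow(registry_B))
  jm <- join_on_key(mrn_a, mrn_b)
  if (nrow(jm)) {
    links$mrn <- data.frame(record_id_A = registry_A$record_id[jm$ia],
                            record_id_B = registry_B$record_id[jm$ib],
                            rule = "MRN", stringsAsFactors = FALSE)
  }

  if (!length(links)) {
    return(data.frame(record_id_A = character(0), record_id_B = character(0),
                      rule = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, links)
  rownames(out) <- NULL
  out
}

global_id <- function(source, record_id) paste(source, record_id, sep = ":")

#' Resolve pairwise links into person clusters
#'
#' Treats records as nodes and links as undirected edges and takes connected
#' components, so linkage is transitive: if one record links to two others,
#' all three records end up in one cluster (a deliberate union policy; the
#' merge is reported because token-based linkage can over-merge when names
#' are similar). Cluster ids are assigned deterministically in the sort
#' order of each component's smallest global record id. Clusters containing
#' at least one record from each health system are flagged as the matched
#' cohort.
#'
#' @param links Data frame of edges with columns `from`, `to` holding global
#'   ids (`"SOURCE:record_id"`), plus a `rule` column kept as evidence.
#' @param records Data frame of all records in scope, columns `source`,
#'   `record_id` (unlinked records become singleton clusters).
#' @param quiet Suppress the multi-way merge message.
#' @return An object of class `person_clusters`: list with `members`
#'   (cluster_id, source, record_id), `evidence` (the input links with
#'   cluster ids), and `matched` (cluster_id, matched flag).
#' @export
resolve_clusters <- function(links, records, quiet = FALSE) {
  stopifnot(all(c("source", "record_id") %in% names(records)))
  gid <- global_id(records$source, records$record_id)
  if (anyDuplicated(gid)) stop("duplicate (source, record_id) pairs in records")

  if (nrow(links)) {
    bad <- !(links$from %in% gid) | !(links$to %in% gid)
    if (any(bad)) stop("links reference unknown records")
    g <- igraph::graph_from_data_frame(
      unique(links[, c("from", "to")]),
      directed = FALSE,
      vertices = data.frame(name = gid, stringsAsFactors = FALSE)
    )
    m <- igraph::components(g)$membership
    comp <- as.integer(m[match(gid, names(m))])
    rm(g, m)
  } else {
    comp <- seq_along(gid)
  }

  ord <- order(gid, method = "radix")
  comp_ord <- comp[ord]
  reps <- comp_ord[!duplicated(comp_ord)] # components ranked by smallest gid
  cl_num <- match(comp, reps)
  cluster_id <- sprintf("C%08d", cl_num)

  members <- data.frame(cluster_id = cluster_id,
                        source = as.character(records$source),
                        record_id = records$record_id,
                        stringsAsFactors = FALSE)
  # several records of one source in one cluster means either a duplicate
  # identity or an over-merge by union; report it (similar names carry a
  # known false-linkage risk)
  over <- unique(cluster_id[duplicated(paste(cluster_id, members$source))])
  if (!quiet && length(over)) {
    message(sprintf(
      "resolve_clusters: %d cluster(s) contain multiple records from one source (union merge)",
      length(over)))
  }
  has_a <- unique(cluster_id[members$source == "SYSTEM_A"])
  has_b <- unique(cluster_id[members$source == "SYSTEM_B"])
  ids <- sort(unique(cluster_id))
  matched <- data.frame(cluster_id = ids,
                        matched = ids %in% has_a & ids %in% has_b,
                        stringsAsFactors = FALSE)

  evidence <- if (nrow(links)) {
    cbind(links,
          cluster_id = cluster_id[match(links$from, gid)],
          stringsAsFactors = FALSE)
  } else {
    cbind(links, cluster_id = character(0))
  }

  structure(list(members = members, evidence = evidence, matched = matched),
            class = "person_clusters")
}

#' @export
print.person_clusters <- function(x, ...) {
  n_cl <- nrow(x$matched)
  cat(sprintf("person_clusters: %d records in %d clusters (%d matched across both systems)\n",
              nrow(x$members), n_cl, sum(x$matched$matched)))
  if (nrow(x$evidence)) {
    tab <- table(x$evidence$rule)
    cat("link evidence:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Link a death-master extract to person clusters
#'
#' Matches each extract record against the token sets of existing clusters.
#' A cluster and an extract record link when token 1 AND token 2 both match,
#' or when any one of tokens 3, 4 or 5 matches (tokens 4 and 5 carry the SSN
#' and are therefore immune to name noise).
#'
#' @param clusters A `person_clusters` object over the two health systems.
#' @param ssadmf Extract data frame (columns as in registries, `source` =
#'   "SSADMF").
#' @param registry_A,registry_B The registries backing `clusters` (needed to
#'   rebuild token material).
#' @param salt Character scalar keying the token digests; must equal the salt
#'   used for any pre-built tokens.
#' @return Data frame of cluster-to-extract links: `cluster_id`,
#'   `record_id_S`, `rule` in {"T1+T2", "T3", "T4", "T5"}.
#' @export
link_ssadmf <- function(clusters, ssadmf, registry_A, registry_B, salt) {
  stopifnot(inherits(clusters, "person_clusters"))
  check_unique_ids(ssadmf, "ssadmf")

  id_cols <- c("record_id", "first_name", "last_name", "gender",
               "birth_date", "ssn")
  with_source <- function(reg, src) {
    out <- reg[, intersect(names(reg), id_cols), drop = FALSE]
    out$source <- rep(src, nrow(out))
    out
  }
  ab <- rbind(with_source(registry_A, "SYSTEM_A"),
              with_source(registry_B, "SYSTEM_B"))
  # cluster of each A/B record, matched per source (no global-id strings)
  mem <- clusters$members
  cl_ab <- rep(NA_character_, nrow(ab))
  for (src in c("SYSTEM_A", "SYSTEM_B")) {
    sel <- ab$source == src
    msel <- mem$source == src
    cl_ab[sel] <- mem$cluster_id[msel][match(ab$record_id[sel],
                                             mem$record_id[msel])]
  }
  s <- ssadmf
  s$source <- rep("SSADMF", nrow(s))
  f_ab <- token_fields(ab)
  f_s <- token_fields(s)

  # one token kind at a time: material -> digest -> digest join, so the full
  # five-kind token table is never held in memory at once
  pairs_for <- function(kind) {
    empty <- data.frame(cluster_id = character(0), record_id_S = character(0),
                        stringsAsFactors = FALSE)
    tm_s <- token_material(f_s, kind)
    if (!length(tm_s$idx)) return(empty)
    tm_ab <- token_material(f_ab, kind)
    ok <- !is.na(cl_ab[tm_ab$idx])
    if (!any(ok)) return(empty)
    ad <- token_digest_dedup(tm_ab$mat[ok], salt)
    acl <- cl_ab[tm_ab$idx][ok]
    smap <- split(s$record_id[tm_s$idx], token_digest(tm_s$mat, salt))
    keep <- which(ad %in% names(smap))
    if (!length(keep)) return(empty)
    dup <- duplicated(paste(acl[keep], ad[keep], sep = "\r"))
    keep <- keep[!dup]
    sl <- smap[match(ad[keep], names(smap))]
    data.frame(cluster_id = rep(acl[keep], lengths(sl)),
               record_id_S = unlist(sl, use.names = FALSE),
               stringsAsFactors = FALSE)
  }

  p <- lapply(c(T1 = "T1", T2 = "T2", T3 = "T3", T4 = "T4", T5 = "T5"), pairs_for)
  key <- function(d) paste(d$cluster_id, d$record_id_S, sep = "\r")
  t12 <- p$T1[key(p$T1) %in% key(p$T2), , drop = FALSE]

  out <- rbind(
    if (nrow(t12)) cbind(t12, rule = "T1+T2", stringsAsFactors = FALSE),
    if (nrow(p$T3)) cbind(p$T3, rule = "T3", stringsAsFactors = FALSE),
    if (nrow(p$T4)) cbind(p$T4, rule = "T4", stringsAsFactors = FALSE),
    if (nrow(p$T5)) cbind(p$T5, rule = "T5", stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(0), record_id_S = character(0),
                      rule = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Run both linkage stages and resolve final clusters
#'
#' Convenience driver: links the two health systems, resolves preliminary
#' clusters, links the death-master extract to those clusters, then resolves
#' the final clusters over all three sources.
#'
#' @inheritParams link_cross_system
#' @inheritParams link_ssadmf
#' @return A `person_clusters` object spanning all three sources.
#' @export
link_records <- function(registry_A, registry_B, ssadmf = NULL,
                         crosswalk = NULL, salt = "deathconcord") {
  ab_links <- link_cross_system(registry_A, registry_B, crosswalk)
  recs_ab <- rbind(
    data.frame(source = "SYSTEM_A", record_id = registry_A$record_id,
               stringsAsFactors = FALSE),
    data.frame(source = "SYSTEM_B", record_id = registry_B$record_id,
               stringsAsFactors = FALSE)
  )
  edges_ab <- if (nrow(ab_links)) {
    data.frame(from = global_id("SYSTEM_A", ab_links$record_id_A),
               to = global_id("SYSTEM_B", ab_links$record_id_B),
               rule = ab_links$rule, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), rule = character(0))
  }
  pre <- resolve_clusters(edges_ab, recs_ab, quiet = TRUE)

  if (is.null(ssadmf) || !nrow(ssadmf)) {
    return(resolve_clusters(edges_ab, recs_ab))
  }

  s_links <- link_ssadmf(pre, ssadmf, registry_A, registry_B, salt)
  # anchor each cluster-level link on the cluster's first member record
  first_member <- pre$members[!duplicated(pre$members$cluster_id), ]
  anchor <- global_id(first_member$source, first_member$record_id)
  names(anchor) <- first_member$cluster_id
  edges_s <- if (nrow(s_links)) {
    data.frame(from = anchor[s_links$cluster_id],
               to = global_id("SSADMF", s_links$record_id_S),
               rule = s_links$rule, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), rule = character(0))
  }
  recs_all <- rbind(recs_ab,
                    data.frame(source = "SSADMF", record_id = ssadmf$record_id,
                               stringsAsFactors = FALSE))
  resolve_clusters(rbind(edges_ab, edges_s), recs_all)
}
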