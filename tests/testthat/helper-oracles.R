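# Independent oracles and small fixture builders shared across tests.

table1_counts <- c(ABS = 209L, AB = 2682L, AS = 1071L, BS = 43L,
                   A_only = 10697L, B_only = 1017L, S_only = 3972L,
                   none = 884890L)

category_triples <- list(
  ABS = c(1, 1, 1), AB = c(1, 1, 0), AS = c(1, 0, 1), BS = c(0, 1, 1),
  A_only = c(1, 0, 0), B_only = c(0, 1, 0), S_only = c(0, 0, 1),
  none = c(0, 0, 0)
)

# brute-force Fleiss oracle: expand the count table into one row per subject
# and count agreeing rater pairs directly (independent of the aggregated
# closed form used by the package)
oracle_fleiss <- function(counts) {
  counts <- counts[names(category_triples)]
  M <- do.call(rbind, rep(category_triples, times = counts))
  agree <- (M[, 1] == M[, 2]) + (M[, 1] == M[, 3]) + (M[, 2] == M[, 3])
  p_obs <- mean(agree / 3)
  p <- mean(M)
  p_exp <- p^2 + (1 - p)^2
  list(p_observed = p_obs, p_expected = p_exp,
       kappa = (p_obs - p_exp) / (1 - p_exp),
       p_all_concur = mean(rowSums(M) %in% c(0, 3)))
}

# hand-buildable person record
person_record <- function(record_id, source, first, last, gender = "F",
                          birth = "1950-06-15", ssn = NA_character_,
                          mrn = NA_character_, death = NA) {
  data.frame(record_id = record_id, source = source, first_name = first,
             last_name = last, gender = gender, birth_date = as.Date(birth),
             ssn = ssn, mrn = mrn,
             death_date = as.Date(if (is.na(death)) NA else death),
             stringsAsFactors = FALSE)
}

# person_clusters object straight from a members table (for detector tests)
make_clusters <- function(members) {
  ids <- sort(unique(members$cluster_id))
  has_a <- unique(members$cluster_id[members$source == "SYSTEM_A"])
  has_b <- unique(members$cluster_id[members$source == "SYSTEM_B"])
  structure(list(
    members = members,
    evidence = data.frame(from = character(0), to = character(0),
                          rule = character(0), cluster_id = character(0),
                          stringsAsFactors = FALSE),
    matched = data.frame(cluster_id = ids,
                         matched = ids %in% has_a & ids %in% has_b,
                         stringsAsFactors = FALSE)
  ), class = "person_clusters")
}

# death-status rows for detector and summary tests
make_status <- function(cluster_id, dA = NA, dB = NA, dS = NA) {
  n <- length(cluster_id)
  as_d <- function(x) as.Date(as.character(rep_len(x, n)))
  dA <- rep_len(dA, n)
  dB <- rep_len(dB, n)
  dS <- rep_len(dS, n)
  data.frame(cluster_id = cluster_id,
             dead_A = !is.na(dA), dead_B = !is.na(dB), dead_S = !is.na(dS),
             death_date_A = as_d(dA), death_date_B = as_d(dB),
             death_date_S = as_d(dS),
             multi_A = logical(n), multi_B = logical(n), multi_S = logical(n),
             stringsAsFactors = FALSE)
}

enc_row <- function(record_id, source, date) {
  data.frame(record_id = record_id, source = source,
             encounter_date = as.Date(date), stringsAsFactors = FALSE)
}
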