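# Packaged name frequency pools for the synthetic cohort generator.
# Drawn in code (no file or network dependency) so that generation is
# seed-reproducible anywhere. Frequencies are coarse Zipf-style weights over
# common US given names and surnames; a handful of entries carry apostrophes,
# spaces or diacritics to exercise name normalization downstream.

.first_names_female <- c(
  "Mary", "Patricia", "Jennifer", "Linda", "Elizabeth", "Barbara", "Susan",
  "Jessica", "Sarah", "Karen", "Lisa", "Nancy", "Betty", "Margaret",
  "Sandra", "Ashley", "Kimberly", "Emily", "Donna", "Michelle", "Carol",
  "Amanda", "Dorothy", "Melissa", "Deborah", "Stephanie", "Rebecca",
  "Sharon", "Laura", "Cynthia", "Kathleen", "Amy", "Angela", "Shirley",
  "Anna", "Brenda", "Pamela", "Emma", "Nicole", "Helen", "Samantha",
  "Katherine", "Christine", "Debra", "Rachel", "Carolyn", "Janet",
  "Catherine", "Maria", "Heather", "Diane", "Ruth", "Julie", "Olivia",
  "Joyce", "Virginia", "Victoria", "Kelly", "Lauren", "Christina", "Joan",
  "Evelyn", "Judith", "Megan", "Andrea", "Cheryl", "Hannah", "Jacqueline",
  "Martha", "Gloria", "Teresa", "Ann", "Sara", "Madison", "Frances",
  "Kathryn", "Janice", "Jean", "Abigail", "Alice", "Julia", "Judy",
  "Sophia", "Grace", "Denise", "Amber", "Doris", "Marilyn", "Danielle",
  "Beverly", "Isabella", "Theresa", "Diana", "Natalie", "Brittany",
  "Charlotte", "Marie", "Kayla", "Alexis", "Lori", "Jos\u00e9fina",
  "Ren\u00e9e", "Mar\u00eda"
)

.first_names_male <- c(
  "James", "Robert", "John", "Michael", "David", "William", "Richard",
  "Joseph", "Thomas", "Charles", "Christopher", "Daniel", "Matthew",
  "Anthony", "Mark", "Donald", "Steven", "Paul", "Andrew", "Joshua",
  "Kenneth", "Kevin", "Brian", "George", "Timothy", "Ronald", "Edward",
  "Jason", "Jeffrey", "Ryan", "Jacob", "Gary", "Nicholas", "Eric",
  "Jonathan", "Stephen", "Larry", "Justin", "Scott", "Brandon", "Benjamin",
  "Samuel", "Gregory", "Alexander", "Frank", "Patrick", "Raymond", "Jack",
  "Dennis", "Jerry", "Tyler", "Aaron", "Jose", "Adam", "Nathan", "Henry",
  "Douglas", "Zachary", "Peter", "Kyle", "Ethan", "Walter", "Noah",
  "Jeremy", "Christian", "Keith", "Roger", "Terry", "Austin", "Sean",
  "Gerald", "Carl", "Harold", "Dylan", "Arthur", "Lawrence", "Jordan",
  "Jesse", "Bryan", "Billy", "Bruce", "Gabriel", "Joe", "Logan", "Alan",
  "Juan", "Albert", "Willie", "Elijah", "Wayne", "Randy", "Vincent",
  "Mason", "Roy", "Ralph", "Bobby", "Russell", "Bradley", "Andr\u00e9s",
  "Ram\u00f3n"
)

.surnames <- c(
  "Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia", "Miller",
  "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez", "Gonzalez",
  "Wilson", "Anderson", "Thomas", "Taylor", "Moore", "Jackson", "Martin",
  "Lee", "Perez", "Thompson", "White", "Harris", "Sanchez", "Clark",
  "Ramirez", "Lewis", "Robinson", "Walker", "Young", "Allen", "King",
  "Wright", "Scott", "Torres", "Nguyen", "Hill", "Flores", "Green",
  "Adams", "Nelson", "Baker", "Hall", "Rivera", "Campbell", "Mitchell",
  "Carter", "Roberts", "Gomez", "Phillips", "Evans", "Turner", "Diaz",
  "Parker", "Cruz", "Edwards", "Collins", "Reyes", "Stewart", "Morris",
  "Morales", "Murphy", "Cook", "Rogers", "Gutierrez", "Ortiz", "Morgan",
  "Cooper", "Peterson", "Bailey", "Reed", "Kelly", "Howard", "Ramos",
  "Kim", "Cox", "Ward", "Richardson", "Watson", "Brooks", "Chavez",
  "Wood", "James", "Bennett", "Gray", "Mendoza", "Ruiz", "Hughes",
  "Price", "Alvarez", "Castillo", "Sanders", "Patel", "Myers", "Long",
  "Ross", "Foster", "Jimenez", "Powell", "Jenkins", "Perry", "Russell",
  "Sullivan", "Bell", "Coleman", "Butler", "Henderson", "Barnes",
  "Gonzales", "Fisher", "Vasquez", "Simmons", "Romero", "Jordan",
  "Patterson", "Alexander", "Hamilton", "Graham", "Reynolds", "Griffin",
  "Wallace", "Moreno", "West", "Cole", "Hayes", "Bryant", "Herrera",
  "Gibson", "Ellis", "Tran", "Medina", "Aguilar", "Stevens", "Murray",
  "Ford", "Castro", "Marshall", "Owens", "Harrison", "Fernandez",
  "McDonald", "Woods", "Washington", "Kennedy", "Wells", "Vargas",
  "Henry", "Chen", "Freeman", "Webb", "Tucker", "Guzman", "Burns",
  "Crawford", "Olson", "Simpson", "Porter", "Hunter", "Gordon", "Mendez",
  "Silva", "Shaw", "Snyder", "Mason", "Dixon", "Munoz", "Hunt", "Hicks",
  "Holmes", "Palmer", "Wagner", "Black", "Robertson", "Boyd", "Rose",
  "Stone", "Salazar", "Fox", "Warren", "Mills", "Meyer", "Rice",
  "Schmidt", "O'Brien", "O'Connor", "McCarthy", "Nu\u00f1ez", "Pe\u00f1a",
  "De La Cruz", "Van Dyke", "St. Clair"
)

# Zipf-style sampling weights: rank r gets weight 1/r, so early (common)
# names dominate as in real registries.
zipf_weights <- function(n) 1 / seq_len(n)

sample_first_names <- function(n, gender) {
  out <- character(n)
  f <- gender == "F"
  m <- gender == "M"
  u <- !f & !m
  pool_f <- .first_names_female
  pool_m <- .first_names_male
  if (any(f)) out[f] <- sample(pool_f, sum(f), TRUE, zipf_weights(length(pool_f)))
  if (any(m)) out[m] <- sample(pool_m, sum(m), TRUE, zipf_weights(length(pool_m)))
  if (any(u)) {
    pool_u <- c(pool_f, pool_m)
    out[u] <- sample(pool_u, sum(u), TRUE, zipf_weights(length(pool_u)))
  }
  out
}

sample_surnames <- function(n) {
  sample(.surnames, n, TRUE, zipf_weights(length(.surnames)))
}
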