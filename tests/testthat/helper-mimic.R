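# Synthetic MIMIC-schema fixture tables, built in code (no real data).

ts <- function(x) as.POSIXct(x, tz = "UTC")

# A small multi-patient fixture:
#  p1: two stays 40 days apart (negative), then readmission within 10 days
#  p2: dies during the stay (excluded)
#  p3: aged 17 at discharge (excluded)
#  p4: dies 20 days after discharge, no readmission (excluded)
#  p5: dies day 20 but was readmitted day 10 (index stay retained+positive)
mimic_fixture <- function() {
  icustays <- data.frame(
    SUBJECT_ID = c(1L, 1L, 1L, 2L, 3L, 4L, 5L, 5L),
    HADM_ID = c(101L, 102L, 103L, 201L, 301L, 401L, 501L, 502L),
    ICUSTAY_ID = c(1001L, 1002L, 1003L, 2001L, 3001L, 4001L, 5001L, 5002L),
    INTIME = ts(c("2130-01-01 10:00:00", "2130-02-15 08:00:00",
                  "2130-02-27 09:00:00", "2131-05-01 00:00:00",
                  "2132-03-01 12:00:00", "2133-07-01 06:00:00",
                  "2134-01-01 10:00:00", "2134-01-15 11:00:00")),
    OUTTIME = ts(c("2130-01-05 16:00:00", "2130-02-17 12:00:00",
                   "2130-03-02 18:00:00", "2131-05-10 00:00:00",
                   "2132-03-05 12:00:00", "2133-07-04 12:00:00",
                   "2134-01-05 09:00:00", "2134-01-18 12:00:00"))
  )
  patients <- data.frame(
    SUBJECT_ID = 1:5,
    GENDER = c("M", "F", "M", "F", "M"),
    DOB = ts(c("2070-01-01", "2090-06-01", "2114-06-01", "2060-01-01",
               "2074-01-01")),
    DOD = ts(c(NA, "2131-05-05", NA, "2133-07-24", "2134-01-25"))
  )
  admissions <- data.frame(
    HADM_ID = c(101L, 102L, 103L, 201L, 301L, 401L, 501L, 502L),
    SUBJECT_ID = c(1L, 1L, 1L, 2L, 3L, 4L, 5L, 5L),
    ADMITTIME = icustays$INTIME - 3600 * 24,
    DISCHTIME = icustays$OUTTIME + 3600 * 36,
    ETHNICITY = c("WHITE", "WHITE", "WHITE", "BLACK/AFRICAN AMERICAN",
                  "ASIAN", "WHITE", "HISPANIC OR LATINO", "HISPANIC OR LATINO"),
    INSURANCE = c("Medicare", "Medicare", "Private", "Medicaid", "Private",
                  "Medicare", "Self Pay", "Self Pay"),
    MARITAL_STATUS = c("MARRIED", "MARRIED", "MARRIED", "SINGLE", "DIVORCED",
                       "WIDOWED", "SINGLE", "SINGLE"),
    ADMISSION_LOCATION = c("EMERGENCY ROOM ADMIT", "EMERGENCY ROOM ADMIT",
                           "PHYS REFERRAL/NORMAL DELI", "CLINIC REFERRAL/PREMATURE",
                           "TRANSFER FROM HOSP/EXTRAM", "EMERGENCY ROOM ADMIT",
                           "EMERGENCY ROOM ADMIT", "EMERGENCY ROOM ADMIT"),
    ADMISSION_TYPE = c("EMERGENCY", "EMERGENCY", "ELECTIVE", "EMERGENCY",
                       "EMERGENCY", "EMERGENCY", "EMERGENCY", "EMERGENCY")
  )
  diagnoses <- data.frame(
    SUBJECT_ID = c(1L, 1L, 1L, 1L, 5L),
    HADM_ID = c(101L, 101L, 102L, 103L, 501L),
    ICD9_CODE = c("4280", "5849", "4280", "0389", "4280")
  )
  procedures <- data.frame(
    SUBJECT_ID = c(1L, 5L),
    HADM_ID = c(101L, 501L),
    ICD9_CODE = c("9671", "3893")
  )
  prescriptions <- data.frame(
    SUBJECT_ID = c(1L, 1L, 5L),
    HADM_ID = c(101L, 102L, 501L),
    ICUSTAY_ID = c(1001L, 1002L, 5001L),
    STARTDATE = ts(c("2130-01-03 10:00:00", "2130-02-16 00:00:00",
                     "2134-01-02 08:00:00")),
    DRUG = c("Furosemide", "Heparin Sodium", "Furosemide")
  )
  chartevents <- data.frame(
    SUBJECT_ID = c(1L, 1L, 1L, 1L, 5L),
    HADM_ID = c(101L, 101L, 101L, 101L, 501L),
    ICUSTAY_ID = c(1001L, 1001L, 1001L, 1001L, 5001L),
    ITEMID = c(211L, 211L, 618L, 676L, 220045L),
    CHARTTIME = ts(c("2130-01-02 08:00:00", "2130-01-02 12:00:00",
                     "2130-01-03 08:00:00", "2130-01-03 09:00:00",
                     "2134-01-02 06:00:00")),
    VALUENUM = c(95, 97, 35, 35.0, 120)
  )
  outputevents <- data.frame(
    SUBJECT_ID = 1L, HADM_ID = 101L, ICUSTAY_ID = 1001L,
    ITEMID = 40055L,
    CHARTTIME = ts("2130-01-02 20:00:00"),
    VALUE = 500
  )
  list(PATIENTS = patients, ADMISSIONS = admissions, ICUSTAYS = icustays,
       DIAGNOSES_ICD = diagnoses, PROCEDURES_ICD = procedures,
       PRESCRIPTIONS = prescriptions, CHARTEVENTS = chartevents,
       OUTPUTEVENTS = outputevents)
}
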