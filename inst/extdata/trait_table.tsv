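trait_id	ukbb_field	domain	label	prev_male	prev_female
social_job	22617	social	Social job (0 = less social job, 1 = more social job)	0.06	0.16
friendship_satisfaction	4570	social	Friendship satisfaction (0 = low satisfaction, 1 = high satisfaction)	0.21	0.24
family_satisfaction	4559	social	Family satisfaction (0 = low satisfaction, 1 = high satisfaction)	0.24	0.23
family_visits	1031	social	Family visits (0 = low number of visits, 1 = high number of visits)	0.34	0.46
living_with_others	709	social	Living with others (0 = living alone, 1 = living with other individuals)	0.85	0.83
household_size	709	social	Household size (0 = living with 3 or fewer housemates, 1 = living with 4+ housemates)	0.22	0.20
siblings	5057	social	Siblings (0 = only child, 1 = has siblings)	0.87	0.88
romantic_partners	2149	social	Romantic partners (0 = one romantic partner, 1 = more than one romantic partners)	0.78	0.75
social_support	2110	social	Social support (0 = low social support, 1 = high social support)	0.54	0.55
sports_club	6160	social	Sports club (0 = not in a sports club, 1 = sports club member)	0.35	0.36
weekly_social_activity	6160	social	Weekly social activity (0 = no weekly social activity, 1 = weekly social activity)	0.72	0.73
loneliness	2020	social	Loneliness (0 = not lonely, 1 = lonely)	0.12	0.18
morning_person	1180	personality	Morning/evening person (0 = evening person, 1 = morning person)	0.64	0.64
mood_swings	1920	personality	Mood swings (0 = no mood swings, 1 = mood swings)	0.37	0.45
miserableness	1930	personality	Miserableness (0 = not miserable, 1 = miserable)	0.33	0.49
irritability	1940	personality	Irritability (0 = not irritable, 1 = irritable)	0.29	0.25
sensitivity	1950	personality	Sensitivity (0 = is not sensitive, 1 = sensitive)	0.44	0.59
fed_up_feelings	1960	personality	Fed-up feelings (0 = does not have fed-up feelings, 1 = has fed-up feelings)	0.32	0.39
nervous	1970	personality	Nervous (0 = not a nervous person, 1 = nervous)	0.17	0.22
worrier	1980	personality	Worrier (0 = not a worrier, 1 = worrier)	0.44	0.60
tense	1990	personality	Tense (0 = not a tense person, 1 = tense)	0.12	0.17
embarrassment	2000	personality	Embarrassment (0 = does not worry too long after embarrassment, 1 = worries after embarrassment)	0.40	0.54
suffers_from_nerves	2010	personality	Suffers from nerves (0 = does not suffer from nerves, 1 = suffers from nerves)	0.19	0.17
guilty	2030	personality	Guilty (0 = is not a guilty person, 1 = guilty)	0.21	0.35
risk_taking	2040	personality	Risk-taking (0 = not a risk-taker, 1 = risk-taker)	0.35	0.20
neuroticism	20127	personality	Neuroticism (0 = low neuroticism, 1 = high neuroticism)	0.27	0.37
happy_mood	4526	personality	Happy mood (0 = unhappy, 1 = happy)	0.81	0.81
age_completed_education	845	demographic	Age completed education (0 = younger age, 1 = older age)	0.22	0.27
vehicles	728	demographic	Vehicles (0 = few vehicles, 1 = many vehicles)	0.61	0.56
income	738	demographic	Income (0 = low income, 1 = high income)	0.32	0.25
job_satisfaction	4537	demographic	Job satisfaction (0 = low satisfaction, 1 = high satisfaction)	0.86	0.84
health_satisfaction	4548	demographic	Health satisfaction (0 = low satisfaction, 1 = high satisfaction)	0.79	0.81
financial_satisfaction	4581	demographic	Financial satisfaction (0 = low satisfaction, 1 = high satisfaction)	0.80	0.82
working_hours	767	demographic	Working Hours (0 = 40 hour work week, 1 = 40+ hour work week)	0.26	0.11
work_home_distance	796	demographic	Distance between work and home (0 = close distance, 1 = far distance)	0.23	0.14
walking_standing_job	806	demographic	Walking or standing job (0 = job involves mostly sitting, 1 = job involves mainly walking or standing)	0.73	0.73
manual_job	816	demographic	Manual job (0 = job does not involve heavy manual or physical work, 1 = job involves heavy or manual work)	0.48	0.49
breastfed_as_infant	1677	demographic	Breastfed as Infant (0 = no, 1 = yes)	0.57	0.58
health_care	4674	demographic	Health care (0 = public health care, 1 = private health care)	0.27	0.26
iq	20016	demographic	IQ (0 = low IQ, 1 = high IQ)	0.20	0.18
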