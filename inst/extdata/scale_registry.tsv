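# apathynet scale registry: one record per questionnaire item.
# Columns: scale, item, domain, reverse (0/1), stem (abbreviated descriptor).
# The AMI key follows the published three-subscale structure (6 items per
# domain). AES and DAS domain labels and reverse flags are best-effort keys
# derived from the original instruments' subscale classifications; they are
# shipped as editable data, not code - correct them here if your copy of the
# instrument differs. Reverse = 1 means the raw response must be re-coded
# (max - response) so that higher always means more apathetic.
scale	item	domain	reverse	stem
AMI	AMI-1	Emotional	0	feels others' sadness
AMI	AMI-2	Social	0	approaches strangers
AMI	AMI-3	Social	0	enjoys meeting new people
AMI	AMI-4	Social	0	suggests shared activities
AMI	AMI-5	Behavioural	0	makes effort when decided
AMI	AMI-6	Emotional	0	moved by acquaintance's misfortune
AMI	AMI-7	Emotional	0	concerned after arguments
AMI	AMI-8	Social	0	values joint activities
AMI	AMI-9	Behavioural	0	completes planned tasks
AMI	AMI-10	Behavioural	0	sees chores through
AMI	AMI-11	Behavioural	0	makes decisions promptly
AMI	AMI-12	Behavioural	0	gets things done daily
AMI	AMI-13	Emotional	0	affected by bad news
AMI	AMI-14	Social	0	starts conversations unprompted
AMI	AMI-15	Behavioural	0	acts on tasks straightaway
AMI	AMI-16	Emotional	0	reacts to emotional events
AMI	AMI-17	Social	0	keeps in touch with friends
AMI	AMI-18	Emotional	0	feels warmth towards others
AES	AES-1	Cognitive	1	interested in things
AES	AES-2	Cognitive	1	gets things done during the day
AES	AES-3	Cognitive	1	self-starts activities
AES	AES-4	Cognitive	1	interested in new experiences
AES	AES-5	Cognitive	1	interested in learning
AES	AES-6	Behavioural	0	puts little effort into things
AES	AES-7	Emotional	1	approaches life with intensity
AES	AES-8	Cognitive	1	sees jobs through to the end
AES	AES-9	Behavioural	1	spends time on hobbies
AES	AES-10	Behavioural	0	needs telling what to do
AES	AES-11	Emotional	0	unconcerned about many things
AES	AES-12	Behavioural	1	has friends
AES	AES-13	Cognitive	1	values getting together with friends
AES	AES-14	Emotional	1	excited by good news
AES	AES-15	Behavioural	1	accurate self-understanding
AES	AES-16	Cognitive	1	finishes what is started
AES	AES-17	Behavioural	1	has initiative
AES	AES-18	Emotional	1	has motivation
DAS	DAS-1	Executive	0	needs reminders for tasks
DAS	DAS-2	Emotional	1	feels emotional
DAS	DAS-3	Initiation	1	plans days ahead
DAS	DAS-4	Executive	1	organises several things at once
DAS	DAS-5	Emotional	1	expresses feelings
DAS	DAS-6	Initiation	0	thinks of nothing to say
DAS	DAS-7	Executive	1	concentrates on tasks
DAS	DAS-8	Emotional	0	indifferent to others' troubles
DAS	DAS-9	Initiation	1	contacts friends
DAS	DAS-10	Executive	0	struggles to plan ahead
DAS	DAS-11	Emotional	1	touched by sad events
DAS	DAS-12	Initiation	1	generates new ideas
DAS	DAS-13	Executive	1	keeps track of ongoing tasks
DAS	DAS-14	Emotional	0	emotionally flat
DAS	DAS-15	Initiation	1	starts new activities
DAS	DAS-16	Executive	0	loses track of instructions
DAS	DAS-17	Emotional	1	shares others' joy
DAS	DAS-18	Initiation	1	keeps busy
DAS	DAS-19	Executive	1	plans tasks in order
DAS	DAS-20	Emotional	0	unmoved by emotional scenes
DAS	DAS-21	Initiation	1	curious about surroundings
DAS	DAS-22	Executive	1	switches between tasks
DAS	DAS-23	Emotional	1	responds to others' feelings
DAS	DAS-24	Initiation	1	seeks out pastimes
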