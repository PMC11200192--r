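allele	short_seq	full_seq
DRB1*07:01	DNFSMKGAFTAEIPEVHIYFSRNICWLLPCNLQN	QCGCETDQWNYHMQHIDLHAMLMTEFTVTSARKRCVGNCDHGASKVECHSTMSWGERMTYKESTQHSLHAYACCYSYGLMFRFVPMSFRERYTVFRILDCWDWKLKQKEIRPVTEGKIRKADSEHLMNYTHCHPICSSAIWRMGTPYFYMVHMRFMLHENHQCWEVDDRRTCSMTEKYKFIQWGYRSSVNMLIQGHRMMITWGGMSWIFSDEDIVMMDFPYWLEDMAKLDHLQCAANVNGAKRLGHWHEWIQVQMVHEQAPAYWSHKFY
DRB1*04:04	DGAIWDVMINKGCERKCPFDKILTNVKFPLPWIH	KDWWICLLVNSLLMTYFITGLLCICPPGVFVGSATEMMECDNWCQKRQRLDEEFSCGTTINAEVVLFSHTFDNESTIGPFRPIQDKLTMQNYGAHAAQDTHASGRFYKKRFWVFSNVDFNMQGMQANGISARLRDNNIPHIGFVGPCEVVYYWQLVVSGDWEKEDPDRIGGFGDMAYATYICCYPLYAVLVNIKHWHWFWSLAGNAAYVSDEVLHPPWARAWARGGEEPMRYGMIPRRYTCMMFSQMEMAPNTREQCHGQQDPQMDHRD
DRB1*15:01	NYGGDMQLYQFSCWSEKKRFPVNIYTQHPSCGFK	VRTNYLIAPHAQENTAPNVHPMAIQIWMTKMGWKIQCRIYAACFMTFAYSMVYTQEADVFEMRPDNLTATVPHYWITVMVFPQQFRWNWIFIYHAGCCMTRTCHRQYCCVDCIPDQLVWFGELDNCELMGRMYTSGFAQEYYASRAKACATHECMSEMLNVRSHYMHCVFEFQDVAGFRYGINNFTMCAMPCDVIGRKEGAECIPQLVRTARSTLWKLHFVGNWQMNVWFREIVFEHLHTSDAEKMLPDYRRKTPKWCVNRWIWNCHVR
DRB1*03:01	KGSMWFWLDAAPPFCGPPYKFNCICNYWTIKHDV	KWAMRQLILVYFCGMEAPQMDDWMYANYPRFEKYNVAIGGEPHYAAPPTNFIWHMWAAHNQEPNHPVQPVTMMLASCTPKIRGMHLMAPFINERDAGSQGIIHHKCDEHSKRVHKCCISQCSQACGNFNYYRCAGTTPWPFAHNPTMQQCMQEGWFDDYSLSNQQNNYQQMTFENYRESVHVSWDQKSQYASIYVKWQEKLPLVSSPCIKLDDCESRHWLGNLEQRILQFRDHSTVANNYQWINDSHDKTNFTVWKRCMKNQTDNTAIW
DQA1*05:01/DQB1*02:01	GDAFWFAQWYEAVSFNFAFFRVRDSVRWLDDAMS	KICPHCFLHYWWIKVIQNWWALDHGCCAEFANESFCCRATDPMESMWDLSMNDLSVSGCKFRDVFQEDCTWQQKLMPVFCQYVVRVNFVWLFTQQVNNGGHKYRAVMREPCESNWESWKPWHAEFKACMTQCWCMVGFKDWTGKSALWRMMVTAKDMCWIIRLLICPLKGFMWHVIPCVDYRAIHSVDEMLELCPCKSVEPTNTDFNEFTKVNYRTLLYRAGGPARRLWGQDANRNRLDHVEAVCRTVTRKATRQRQKFVEHTYENYPA
DPA1*01:03/DPB1*04:01	ILRSNIRAYEMKMMGSHARCAYQRREMLCHMNYP	CGQSITNLRHHFCYSYCCRTHDHVRFCCQPHDMGVITLIAYALLWIQDNQKSNQDLMETIQWDKANVKHVIMTSALYPVIVSAYVNYEFHSEQKQMWYMSLKRGHFEEHGAWGWNPEAYVDFFCWIHDANIRFVVMCNSCPCDWPEDLNMNYEEDGNKLKTYQICMDKATTLNGNYYCYSWRTQKTMARIHCEMDHKPWQEQTDLCYQYRNIHHHQVKAIPMPPIHMECGLQSYGCTANFPGNRDCKNVEIVAERMYTSTCAVVHLLCH
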