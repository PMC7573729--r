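>qa_g1
YSSAFLRTNIKFLRGMTNVRVPEQEPRLKGLRRQDRRNTVPIEDAYESPCTIWGDARRHQTGIRTRTWIWGPARTEAHVYMYPDRVYCMYGRQGSFYARDVFRGTFFVVYILLNVFWIIRRSFCPCMLCCRKQACGYAVCLYLRILYPRCDQGLVVIDQAQTSNMWSWAKKLHSDPQPDSRAGELNQAGSLECDYGTAIAFPGHKTPAKWRPPLTKDVGIHLLSRCTCPASPEQFSRLKPSKKVHDENWQHSYRFRARLHWGWMGCTSRHNEFVLLDCAFPRWVRVCGPRYNALFAYRRV
>qa_g5
YSSAFLRTNIKFLRGITNVRVPEQEPRLKGLRRQDRRNTVPIEDAFESPCTIWGDALRHQTGIRSRTWLRGPAWPEAHVYIYPDRVYSMDGRQGSLYARDVFRGTFFVVYILLNVFWIIRRSFCPCMLCCWKQACGYAVSLYLRILYPRCDQGLVVIDQAQTSNMWSWAKKLHSDPLPDSRAGELNQAGSRECDYGTAIAFPGRKTPAKWRPPLTKDLGKHLLCRCTCPASPEQFRTLKPSKKVHNDNWQHSYRFRPSLHWGWMGCTSRHDEFVLLDCAFPRWVRFCGPRYNALFAYRRV
>qa_g6
YSSAFLRTNTKFLRGITNVRVPEQEPRLKGLRRQDRRNTVPIEDVFESPCTIWGDALRHQTGIGSRTWLRGPAWPEAHVYIYPDRVYSMDGRQGSLYARDVFRGTFFVVYILLNVFWIIRRSFCPCMLCCWKQACGYAVSLYLRILYPRCDQGLVVIDQAQTSNMWSWAKKLHSDPLPDSRAGELNQAGSGECDYGTAIAFPGRKTPTKWRPPLTKDLGIHLLCRCTCPASPEQFRTLKPSKKVHNDNWQHSYRFRPRLHWGWMGCTSRHDEFVLLDCALPRWVRFCGPRYNALFAYRRV
>qa_g2
YSSAFLRTNIKFLRGITNVRVPEQEPRLKGLRRQDRRNTVPIEDAFESPCTIGGDALRHQTGIRSRTWLRGPAWPEAHVYIYPDRVYSMDGRQGSLYARDVFRGTIFVFYILLNVFWIIRRSFCPCMLCCWKQACGYAVSLYRRILYPRCDQGLVVIDQAQTRNMWSWAKKLHSDPQPDSRAGELNQAGSRECDYGTAIAFPGHKTPAKWRPPLTKDLGIHLLCRCTCPASPEQFRRLKPSKKVYNDNWQHSYRFRARLHWGWMGCTSRHYEFVLLDCAFPRWVRLCGPRYNALFAYRRV
>qa_g3
YSSAFLRTNIKYLRGITNDRVPGQEPRLKRLCRQDRRSTVPIEDAFKSPCTIWGDALRHQTGIRSRTWLRGPARPEAHVYIYLDRVYSMDGRQGSFYARDVFRGTFFVVYILLNVFWIIRRSFCLCMLCCWKQACGYAVSLYLPTLYPRCDQGLVDIDQAQTSNMWSRAKKLHSDPQPDSRAGELNQDGSLECDYGTAIAFPGYKTPAKWRPLLTKDVGIHLLCRCTCPASPEQFRRLKPSNKVHDENSQHSYRFRTRLHWVWMGCTSRHNDFVLLDCAFPRWVRFCGPRYNALFAYRRV
>qa_g4
YSSAFLRTNIKYLRGITNDRVPEHEPRLKRLPRQDRRSTVPIEDAFKSPCTIWGDALRHQTGIRSRTWLRGPARPEAHVYIYLDRVYSMDGRQGSFYARDVFRGTFFVVYILLNVFWIIRRSFCLCMLRCWKQACCYAVSLYLRTLYPRCDQGLVDIDLAQTSNMWSRAKKFHSDPQPDSRAGELNQDGSLECDYGTAIAFPGYKTPAKWRPLLTKDVGIHLLCRCTYPASPEQFRRLKPSKKVHDENSQHSYRFRTRLHWVWMGCTSRHNDFVLWDCAFPRWVRFCGPRYNALFAYRRV
>qa_g7
YSPAFLRTNVKFLRGMTNDRVPEQEPCLRGLRRQDRRNTVPIEDAFVSPCTLWGDALKHQTGISSRTWLRGPARPEAHVYIYPDRVYSMDGHQVSFYARDVIRGTFIAVYILLNVFWIIRRSFRLCMLRCLKQACGYAVSLYLRILYPRCDQGLVVMNQAQTSNMWGWATKLHSDQQPGSRARELYQDRSLECDYGTAIAFPGHKMPVKRRPPLTKDEGIHLLCRCTCPASPEQFGRLKPSKEVHNENWQHSYRFRAGLHWGWIGCTSRHDEFVLLDCAFPRWVRFCGPRHNALSGYRRA
>qa_g8
YSPAFLRTNVKFLRGMTNDRVPEQEPCLRGLRRQDRRNTVPIEDAFVSPCTLWGDALKHQTGISSRTWLRGPARPEAHVYIYPDRVYSMDGHQVSFYARDVIRGTFIAVYILLNVFWIIRRSFRLCMLRCLKQACGYAVSLYLRILYPRCDQGLVVMNQAQTSNMWGWATKLHSDQQPGSRARELYQDRSLECDYGTAIAFPGHKMPVKRRPPLTKDVGIHLLCRCTCPASPEQFGRLKPSKEVHNENWQHSYRFRAGLHWGWIGCTSRHDEFVLLDCAFPRWVRFCGPRHNALFGYRRA
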